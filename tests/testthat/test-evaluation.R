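test_that("the F1 score follows its defining arithmetic", {
  expect_equal(f1_score(5, 0, 0), 1)
  expect_equal(f1_score(0, 3, 2), 0)
  # TP = 3, FP = 1, FN = 1: p = r = 0.75 so F1 = 0.75
  expect_equal(f1_score(3, 1, 1), 0.75)
  # symmetric in exchanging precision and recall (swap FP and FN)
  expect_equal(f1_score(4, 2, 7), f1_score(4, 7, 2))
  expect_error(f1_score(-1, 0, 0), "non-negative")
})

test_that("detection classification matches hand-computed tables", {
  toy <- data.frame(
    h2 = 0.5, hf2 = 0.5, n_rep = 5, causal_model = "random",
    dataset = rep(1:2, each = 5),
    feature = rep(c("f0", "f1", "f2", "n1", "n2"), 2),
    feature_type = rep(c("causal", "causal", "causal", "null", "null"), 2),
    dilution = rep(c(0, 100, 200, NA, NA), 2), size = 100,
    statistic = "cvat",
    p_empirical = c(0.01, 0.02, 0.20, 0.50, 0.01,   # dataset 1
                    0.03, 0.50, 0.60, 0.70, 0.80),  # dataset 2
    stringsAsFactors = FALSE)
  per_dil <- classify_detections(toy, alpha = 0.05, by = "dilution")
  # dilution 0: both datasets detected; dilution 100: one; 200: none
  expect_equal(per_dil$TP, c(2, 1, 0))
  expect_equal(per_dil$FP, rep(1, 3))
  expect_equal(per_dil$F1[1], f1_score(2, 1, 0))
  # averaging mode: dataset 1 mean p = 0.0767 (detected), dataset 2
  # mean p = 0.3767 (not detected)
  avg <- classify_detections(toy, alpha = 0.1, by = "average")
  expect_equal(avg$TP, 1)
  expect_equal(avg$FN, 1)
  expect_equal(avg$F1, f1_score(1, 1, 1))
  expect_error(classify_detections(toy[toy$feature_type == "causal", ]),
               "null sets")
})

test_that("false positives occur at the nominal rate under a uniform null", {
  set.seed(601)
  nn <- 4000
  toy <- data.frame(
    dataset = 1, feature = paste0("n", 1:nn), feature_type = "null",
    dilution = NA, statistic = "cvat", p_empirical = runif(nn),
    stringsAsFactors = FALSE)
  toy <- rbind(toy, data.frame(dataset = 1, feature = "f", feature_type =
    "causal", dilution = 0, statistic = "cvat", p_empirical = 0.01,
    stringsAsFactors = FALSE))
  met <- classify_detections(toy, alpha = 0.05)
  expect_lt(abs(met$FP / nn - 0.05), 0.015)
})

test_that("predictive ability is deterministic, bounded and signal-sensitive", {
  tf <- tiny_fit()
  geno <- tf$geno
  f_causal <- feature_set(tf$causal$C1, "causal")
  pa1 <- gfblup_cv_predictive_ability(tf$phe$y, tf$phe$line, geno, f_causal,
                                      n_folds = 6, seed = 11)
  pa2 <- gfblup_cv_predictive_ability(tf$phe$y, tf$phe$line, geno, f_causal,
                                      n_folds = 6, seed = 11)
  expect_identical(pa1$fold_cor, pa2$fold_cor)
  expect_true(all(abs(pa1$fold_cor) <= 1, na.rm = TRUE))
  expect_true(pa1$pa >= -1 && pa1$pa <= 1)
})

test_that("a causal feature usually out-predicts a size-matched random one", {
  geno <- tiny_panel()
  set.seed(602)
  wins <- vapply(1:8, function(i) {
    cc <- select_causal_sets(geno, n_c1 = 30, n_c2 = 120,
                             null_set_sizes = c(40), seed = 700 + i)
    phe <- simulate_phenotypes(geno, cc,
                               simulation_scenario(0.5, 0.5, 4),
                               seed = 800 + i)
    pa_c <- gfblup_cv_predictive_ability(phe$y, phe$line, geno, cc$C1,
                                         n_folds = 8, seed = i)$pa
    rnd <- sample(setdiff(seq_len(1500), cc$C1), 30)
    pa_r <- gfblup_cv_predictive_ability(phe$y, phe$line, geno, rnd,
                                         n_folds = 8, seed = i)$pa
    pa_c > pa_r
  }, logical(1))
  expect_gte(mean(wins), 0.6)
})

test_that("significance-PA correlation has its analytic limits", {
  p <- c(0.5, 0.1, 0.01, 0.3, 0.05)
  pa_monotone <- -log(p) * 0.1 + 0.2   # strictly monotone in -log p
  expect_equal(significance_vs_pa(p, pa_monotone), 1)
  set.seed(603)
  p_many <- runif(300)
  expect_lt(abs(significance_vs_pa(p_many, sample(p_many))), 0.15)
  expect_error(significance_vs_pa(c(0.1, 0.2), c(0.3, 0.4)), "at least 3")
})
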