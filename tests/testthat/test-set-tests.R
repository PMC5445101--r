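eng <- function(n = 300, seed = 7) null_engine(n_perm = n, seed = seed)

test_that("contribution sums reproduce the covariance statistic directly", {
  tf <- tiny_fit()
  contrib <- per_marker_contributions(tf$eff, tf$geno, "cvat")
  # feature = all markers: sum equals ||g_hat||^2 >= 0
  expect_equal(sum(contrib), sum(tf$fit$g_total^2), tolerance = 1e-10)
  expect_gte(sum(contrib), 0)
  # direct evaluation on a small feature: g_hat' (W_f s_f)
  f <- tf$causal$C1[1:10]
  gf <- drop(tf$geno$W[, f] %*% tf$eff$s_hat[f])
  expect_equal(sum(contrib[f]), sum(tf$fit$g_total * gf), tolerance = 1e-12)
})

test_that("the CVAT decomposition identity holds and is checked", {
  tf <- tiny_fit()
  f <- feature_set(tf$causal$C1, "C1")
  res <- cvat(tf$eff, tf$geno, f, eng())
  expect_equal(unname(sum(res$decomposition)), res$observed,
               tolerance = 1e-10)
  expect_true(res$p_empirical > 0 && res$p_empirical <= 1)
})

test_that("the score statistic agrees between its quadratic-form and residual forms", {
  tf <- tiny_fit()
  fit <- tf$fit
  geno <- tf$geno
  f <- tf$causal$C1
  res <- score_test(fit, geno, f, eng())
  # dense quadratic form at observation level:
  # T = 1/2 (y - Xb)' V^-1 G_f V^-1 (y - Xb) with V = Z G Z' sg + I se
  n <- n_lines(geno)
  li <- tf$phe$line
  Zm <- matrix(0, length(tf$phe$y), n)
  Zm[cbind(seq_along(li), li)] <- 1
  G <- build_grm(geno)$G
  V <- fit$vc$sigma_g2[1] * Zm %*% tcrossprod(G, Zm) +
    fit$vc$sigma_e2 * diag(length(li))
  r <- tf$phe$y - drop(fit$X %*% fit$b_hat)
  Vir <- solve(V, r)
  G_f <- build_grm(geno, f)$G
  T6 <- 0.5 * drop(crossprod(Vir, Zm %*% G_f %*% crossprod(Zm, Vir)))
  expect_equal(res$observed, T6, tolerance = 1e-8)
  # per-marker expansion: T = 1/(2 m_f) sum (e_bar' w_i)^2
  u <- drop(crossprod(geno$W[, f], fit$e_bar))
  expect_equal(res$observed, sum(u^2) / (2 * length(f)), tolerance = 1e-8)
})

test_that("excluding the feature from the null model is supported and guarded", {
  tf <- tiny_fit()
  f <- tf$causal$C1
  expect_message(
    res <- score_test(tf$fit, tf$geno, f, eng(), null_model = "exclude_feature"),
    "refitting")
  expect_true(res$p_empirical > 0)
  allf <- seq_len(n_markers(tf$geno))
  expect_error(score_test(tf$fit, tf$geno, allf, eng(),
                          null_model = "exclude_feature"), "all markers")
})

test_that("gamma moment matching has its closed-form limits", {
  # var = mean^2 (shape 1): exponential tail
  expect_equal(satterthwaite_gamma_p(3, 2, 4), exp(-3 / 2), tolerance = 1e-12)
  # concentration: observed at the mean, vanishing relative variance -> 1/2
  p <- satterthwaite_gamma_p(1, 1, 1e-9)
  expect_equal(p, 0.5, tolerance = 0.01)
  expect_error(satterthwaite_gamma_p(1, 0, 1), "positive")
})

test_that("the gamma approximation tracks the permutation p for the score test", {
  tf <- tiny_fit()
  set.seed(120)
  pool <- seq_len(n_markers(tf$geno))
  diffs <- vapply(1:25, function(i) {
    f <- sample(pool, 60)
    res <- score_test(tf$fit, tf$geno, f, null_engine(n_perm = 2000, seed = i))
    res$p_empirical - res$p_parametric
  }, numeric(1))
  expect_lt(stats::median(abs(diffs)), 0.02)
})

test_that("the sum test equals a naive loop and handles singletons", {
  tf <- tiny_fit()
  f <- sort(sample(seq_len(1500), 400))
  res <- sum_test(tf$eff, tf$geno, f, basis = "s2", engine = eng())
  expect_equal(res$observed, sum(vapply(f, function(i) tf$eff$s_hat[i]^2,
                                        numeric(1))), tolerance = 1e-12)
  res_t <- sum_test(tf$eff, tf$geno, f, basis = "t2", engine = eng())
  expect_equal(res_t$observed, sum(tf$eff$t_stat[f]^2), tolerance = 1e-12)
  single <- sum_test(tf$eff, tf$geno, f[1], basis = "s2", engine = eng())
  expect_equal(single$observed, tf$eff$s_hat[f[1]]^2)
})

test_that("the count test matches exact hypergeometric enumeration", {
  # m = 10, m_a = 4, m_f = 5, T = 3: P(X >= 3) = 66/252
  expect_equal(phyper(2, 4, 6, 5, lower.tail = FALSE), 66 / 252)
  # package path on a constructed instance with the same configuration
  set.seed(130)
  A <- matrix(rbinom(120, 2, 0.4), 12, 10)
  A[1, ] <- 1  # guarantees every column polymorphic with MAF >= 0.05
  geno <- genotype_data(A)
  m <- n_markers(geno)
  expect_equal(m, 10)
  t_stat <- rep(0.1, m)
  sig <- c(1, 2, 3, 6)
  t_stat[sig] <- 5  # m_a = 4 markers beyond any reasonable threshold
  eff <- structure(list(s_hat = t_stat, var_s = rep(1, m), t_stat = t_stat,
                        p_single = 2 * pt(-abs(t_stat), 20), df_e = 20,
                        component = rep(1L, m), flagged = rep(FALSE, m),
                        marker_id = geno$marker_ids, chrom = geno$chrom,
                        pos = geno$pos, lines_obs = 1:12),
                   class = "marker_effects")
  f <- c(1, 2, 3, 4, 5)  # contains 3 of the 4 associated markers
  res <- count_test(eff, geno, f, t0 = 2, engine = eng(150))
  expect_equal(res$observed, 3)
  expect_equal(res$p_parametric, 66 / 252)
  expect_equal(res$m_a, 4)
  # all associated markers inside the feature: minimum attainable tail
  res2 <- count_test(eff, geno, c(1, 2, 3, 6), t0 = 2, engine = eng(150))
  expect_equal(res2$observed, 4)
  expect_equal(res2$p_parametric,
               phyper(3, 4, m - 4, 4, lower.tail = FALSE))
  # no marker exceeds the threshold
  expect_warning(res3 <- count_test(eff, geno, f, t0 = 10, engine = eng(150)),
                 "no associated")
  expect_equal(res3$observed, 0)
  expect_equal(res3$p_parametric, 1)
})

test_that("gene-level decomposition is additive on disjoint partitions", {
  tf <- tiny_fit()
  f_idx <- tf$causal$C1
  genes <- split(f_idx, rep(1:3, length.out = length(f_idx)))
  names(genes) <- paste0("gene", 1:3)
  f <- feature_set(f_idx, "C1", genes = genes)
  dec <- cvat_decompose(tf$eff, tf$geno, f)
  expect_equal(sum(dec$T_gene), attr(dec, "feature_T"), tolerance = 1e-10)
  expect_false(attr(dec, "overlapping"))
  # single-SNP gene: per-SNP value equals the raw contribution
  g1 <- feature_set(f_idx[1:2], "f2",
                    genes = list(a = f_idx[1], b = f_idx[2]))
  dec1 <- cvat_decompose(tf$eff, tf$geno, g1)
  expect_equal(dec1$T_per_snp, dec1$T_gene)
  # overlapping genes are evaluated independently and flagged
  ov <- feature_set(f_idx, "ov",
                    genes = list(a = f_idx[1:20], b = f_idx[10:30]))
  deco <- cvat_decompose(tf$eff, tf$geno, ov)
  expect_true(attr(deco, "overlapping"))
  contrib <- per_marker_contributions(tf$eff, tf$geno, "cvat")
  expect_equal(deco$T_gene[1], sum(contrib[f_idx[1:20]]), tolerance = 1e-12)
})

test_that("multi-trait covariance statistics expand per marker", {
  set.seed(140)
  geno <- tiny_panel()
  G <- build_grm(geno)
  n <- n_lines(geno)
  eg <- eigen(G$G, symmetric = TRUE)
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)))
  z <- rnorm(n)
  g1 <- sqrt(30) * drop(L %*% z)
  g2 <- sqrt(30) * drop(L %*% (0.7 * z + sqrt(1 - 0.49) * rnorm(n)))
  fit2 <- suppressWarnings(fit_multitrait(g1 + rnorm(n, 0, 6),
                                          g2 + rnorm(n, 0, 6), G = G))
  f <- feature_set(1:120, "f")
  res <- mt_cvat(fit2, geno, f, eng(150))
  expect_named(res, c("CVAT_M", "CVAT_F", "CVAT_MF", "CVAT_FM"))
  # expansion oracle: T_MF = g1_hat' (W_f s2_f)
  effs <- mt_backsolve_effects(fit2, geno)
  gf2 <- drop(geno$W[, 1:120] %*% effs$t2$s_hat[1:120])
  expect_equal(res$CVAT_MF$observed, sum(fit2$g_hat[, 1] * gf2),
               tolerance = 1e-10)
  # feature covering the genome: T_MF = g1_hat' g2_hat
  allf <- feature_set(seq_len(n_markers(geno)), "all")
  res_all <- mt_cvat(fit2, geno, allf, eng(120))
  expect_equal(res_all$CVAT_MF$observed,
               sum(fit2$g_hat[, 1] * fit2$g_hat[, 2]), tolerance = 1e-8)
  # trait 2 an exact copy of trait 1: across-trait equals within-trait
  ydup <- g1 + rnorm(n, 0, 6)
  fit_dup <- suppressWarnings(fit_multitrait(ydup, ydup, G = G))
  res_dup <- mt_cvat(fit_dup, geno, f, eng(120))
  expect_equal(res_dup$CVAT_MF$observed, res_dup$CVAT_M$observed,
               tolerance = 1e-6)
})

test_that("set statistics ignore the ordering of feature indices", {
  tf <- tiny_fit()
  f <- sample(tf$causal$C1)
  r1 <- cvat(tf$eff, tf$geno, f, eng())
  r2 <- cvat(tf$eff, tf$geno, rev(f), eng())
  expect_identical(r1$observed, r2$observed)
  expect_identical(r1$p_empirical, r2$p_empirical)
})
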