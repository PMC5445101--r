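test_that("inbred panels are homozygous with MAF above the filter", {
  geno <- tiny_panel()
  expect_true(all(geno$A %in% c(0, 2)))
  expect_true(all(geno$p >= 0.05))
  expect_equal(n_markers(geno), 1500)
  expect_equal(n_lines(geno), 60)
  # outbred mode produces heterozygotes
  out <- simulate_genotypes(n_lines = 50, m = 600, inbred = FALSE, seed = 301)
  expect_true(any(out$A == 1))
})

test_that("linkage disequilibrium is concentrated within haplotype blocks", {
  geno <- tiny_panel()
  set.seed(302)
  # nearby markers usually share a haplotype block of ~50 markers
  within <- vapply(1:200, function(i) {
    b <- sample.int(n_markers(geno) - 8, 1)
    cor(geno$A[, b], geno$A[, b + 8])^2
  }, numeric(1))
  between <- vapply(1:200, function(i) {
    idx <- sample.int(1500, 2)
    cor(geno$A[, idx[1]], geno$A[, idx[2]])^2
  }, numeric(1))
  expect_gt(mean(within), mean(between) + 0.1)
})

test_that("causal configurations satisfy the design arithmetic", {
  geno <- tiny_panel()
  cc <- select_causal_sets(geno, "random", n_c1 = 30, n_c2 = 120,
                           null_set_sizes = c(40, 40, 80), seed = 303)
  expect_length(cc$C1, 30)
  expect_length(cc$C2, 120)
  expect_length(intersect(cc$C1, cc$C2), 0)
  for (ns in cc$null_sets) {
    expect_length(intersect(ns, c(cc$C1, cc$C2)), 0)
  }
  # the default configuration uses the study's 100 + 900 split
  geno_big <- fixture("mid_panel", function() {
    simulate_genotypes(n_lines = 40, m = 9000, n_chrom = 3, seed = 304)
  })
  cc_def <- select_causal_sets(geno_big, "random", seed = 305)
  expect_length(cc_def$C1, 100)
  expect_length(cc_def$C2, 900)
  expect_length(cc_def$null_sets, 10)
})

test_that("the cluster model draws C1 from contiguous genome regions", {
  geno <- fixture("mid_panel", function() {
    simulate_genotypes(n_lines = 40, m = 9000, n_chrom = 3, seed = 304)
  })
  cc <- select_causal_sets(geno, "cluster", seed = 306)
  expect_length(cc$regions, 20)
  # each region spans 50 consecutive markers and contributes 5 of them
  for (r in cc$regions) {
    expect_equal(length(r), 50)
    expect_equal(max(r) - min(r) + 1, 50)
    expect_equal(sum(cc$C1 %in% r), 5)
  }
  # regions do not overlap
  expect_equal(anyDuplicated(unlist(cc$regions)), 0)
})

test_that("phenotypes realise the prescribed variance decomposition", {
  geno <- tiny_panel()
  cc <- select_causal_sets(geno, n_c1 = 30, n_c2 = 120,
                           null_set_sizes = c(40), seed = 307)
  vars <- vapply(1:10, function(i) {
    phe <- simulate_phenotypes(geno, cc, simulation_scenario(0.4, 0.3, 5),
                               seed = 400 + i)
    var(phe$y)
  }, numeric(1))
  expect_lt(abs(mean(vars) - 100), 20)
  # zero heritability: phenotypes are pure noise
  phe0 <- simulate_phenotypes(geno, cc, simulation_scenario(0, 0.3, 5),
                              seed = 410)
  expect_identical(attr(phe0, "g1"), numeric(60))
  expect_identical(attr(phe0, "g2"), numeric(60))
  # the feature share of genetic variance tracks hf2
  ratios <- vapply(1:30, function(i) {
    phe <- simulate_phenotypes(geno, cc, simulation_scenario(0.5, 0.3, 5),
                               seed = 500 + i)
    var(attr(phe, "g1")) / (var(attr(phe, "g1")) + var(attr(phe, "g2")))
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.3), 0.1)
})

test_that("scenario variance components follow the stated decomposition", {
  sc <- simulation_scenario(h2 = 0.3, hf2 = 0.2, n_rep = 10)
  expect_equal(sc$sigma_g1_2, 0.3 * 0.2 * 100)
  expect_equal(sc$sigma_g2_2, 0.3 * 0.8 * 100)
  expect_equal(sc$sigma_e_2, 0.7 * 100)
  expect_equal(sc$sigma_g1_2 + sc$sigma_g2_2 + sc$sigma_e_2, sc$sigma_P2)
})

test_that("dilution augments the causal feature with disjoint markers", {
  geno <- tiny_panel()
  cc <- select_causal_sets(geno, n_c1 = 30, n_c2 = 120,
                           null_set_sizes = c(40), seed = 308)
  f0 <- dilute_feature(cc, 0, geno)
  expect_setequal(f0$marker_idx, cc$C1)
  f <- dilute_feature(cc, 200, geno, seed = 309)
  expect_length(f$marker_idx, 230)
  expect_length(intersect(f$marker_idx, cc$C2), 0)
  expect_true(all(cc$C1 %in% f$marker_idx))
  expect_error(dilute_feature(cc, 1e6, geno, seed = 310), "insufficient")
})

test_that("the factorial grid enumerates the full design", {
  expect_equal(nrow(scenario_grid()), 1440)
  reduced <- scenario_grid(h2 = c(0.1, 0.5), hf2 = c(0.1, 0.5),
                           n_rep = c(5, 50), causal_model = "random",
                           dilution = c(0, 500, 2000))
  expect_equal(nrow(reduced), 24)
})

test_that("grid runs are reproducible from the master seed", {
  geno <- tiny_panel()
  grid <- scenario_grid(h2 = 0.5, hf2 = 0.5, n_rep = 5,
                        causal_model = "random", dilution = c(0, 100))
  run <- function() {
    run_scenario_grid(geno, grid, n_datasets = 2,
                      statistics = c("cvat", "score"), n_perm = 200,
                      null_set_sizes = c(40, 40), seed = 99)
  }
  r1 <- run()
  r2 <- run()
  expect_identical(r1, r2)
  expect_setequal(unique(r1$feature_type), c("causal", "null"))
  expect_equal(nrow(r1), 2 * (2 + 2) * 2)  # datasets x features x statistics
})
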