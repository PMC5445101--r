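test_that("REML matches a dense grid search of the restricted likelihood", {
  set.seed(11)
  n <- 24
  geno <- random_genotypes(n, 300, seed = 12)
  G <- build_grm(geno)$G
  g <- drop(chol(G + 1e-6 * diag(n)) %*% rnorm(n)) * 4
  y <- 3 + g + rnorm(n, 0, 2)
  X <- matrix(1, n, 1)
  fit <- fit_gblup(y, X = X, G = G)

  # independent oracle: restricted log-likelihood evaluated on a dense grid
  rl <- function(sg, se) {
    V <- sg * G + se * diag(n)
    Vi <- solve(V)
    XtViX <- crossprod(X, Vi %*% X)
    P <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
    -0.5 * (determinant(V)$modulus + log(XtViX) + sum(y * (P %*% y)))
  }
  sg_grid <- seq(0.2, 15, length.out = 60)
  se_grid <- seq(0.2, 15, length.out = 60)
  ll <- outer(sg_grid, se_grid, Vectorize(rl))
  best <- arrayInd(which.max(ll), dim(ll))
  step <- c(diff(sg_grid)[1], diff(se_grid)[1])
  expect_lt(abs(fit$vc$sigma_g2 - sg_grid[best[1]]), 1.5 * step[1])
  expect_lt(abs(fit$vc$sigma_e2 - se_grid[best[2]]), 1.5 * step[2])
  # and the fit's likelihood is at least the best grid value
  expect_gte(fit$vc$loglik, max(ll) - 1e-6)
})

test_that("a noise-free phenotype drives both variances to the boundary", {
  geno <- random_genotypes(15, 100, seed = 3)
  G <- build_grm(geno)$G
  X <- cbind(1, rnorm(15))
  y <- drop(X %*% c(2, -1))
  fit <- suppressWarnings(fit_gblup(y, X = X, G = G))
  expect_true(fit$boundary)
  expect_lt(fit$vc$sigma_g2, 1e-4)
  expect_lt(fit$vc$sigma_e2, 1e-4)
  expect_lt(max(abs(fit$g_total)), 1e-4)
})

test_that("the accepted likelihood trajectory is non-decreasing", {
  tf <- tiny_fit()
  expect_true(all(diff(tf$fit$ll_trace) >= -1e-9))
})

test_that("BLUP solutions satisfy the mixed-model equations", {
  set.seed(21)
  n <- 40
  geno <- random_genotypes(n, 200, seed = 22)
  G <- build_grm(geno)$G + 0.05 * diag(n)  # positive definite variant
  y <- drop(chol(G) %*% rnorm(n)) + rnorm(n, 0, 1.5)
  X <- cbind(1, runif(n))
  fit <- fit_gblup(y, X = X, G = G)
  sg <- fit$vc$sigma_g2
  se <- fit$vc$sigma_e2
  # MME for Z = I: [X'X  X'; X  I + G^-1 se/sg] [b; g] = [X'y; y]
  C <- rbind(cbind(crossprod(X), t(X)),
             cbind(X, diag(n) + solve(G) * se / sg))
  rhs <- c(crossprod(X, y), y)
  sol <- solve(C, rhs)
  expect_lt(max(abs(sol[1:2] - fit$b_hat)), 1e-6)
  expect_lt(max(abs(sol[-(1:2)] - fit$g_total)), 1e-6)
})

test_that("the collapsed line-mean path equals the dense observation fit", {
  geno <- tiny_panel()
  G <- build_grm(geno)
  causal <- select_causal_sets(geno, n_c1 = 20, n_c2 = 80,
                               null_set_sizes = c(50), seed = 31)
  phe <- simulate_phenotypes(geno, causal,
                             simulation_scenario(0.4, 0.5, n_rep = 4),
                             seed = 32)
  fitC <- fit_gblup(phe$y, Z = phe$line, G = G)
  expect_true(fitC$collapsed)
  # dense fit assembled through the same engine at observation level
  n <- n_lines(geno)
  Zm <- matrix(0, length(phe$y), n)
  Zm[cbind(seq_along(phe$y), phe$line)] <- 1
  K <- list(Zm %*% tcrossprod(G$G, Zm), rep(1, length(phe$y)))
  res <- gblupset:::reml_ai(phe$y, matrix(1, length(phe$y), 1), K,
                            c(TRUE, TRUE))
  expect_equal(unname(fitC$vc$sigma_g2), res$theta[1], tolerance = 1e-4)
  expect_equal(fitC$vc$sigma_e2, res$theta[2], tolerance = 1e-4)
  e_bar_dense <- drop(crossprod(Zm, res$Py))
  expect_lt(max(abs(e_bar_dense - fitC$e_bar)), 1e-5)
  expect_equal(fitC$df_e, res$theta[2] * sum(diag(res$P)), tolerance = 1e-6)
})

test_that("heritability is recovered without systematic bias", {
  geno <- tiny_panel()
  G <- build_grm(geno)
  h2_hat <- vapply(1:8, function(i) {
    causal <- select_causal_sets(geno, n_c1 = 20, n_c2 = 80,
                                 null_set_sizes = c(50), seed = 40 + i)
    phe <- simulate_phenotypes(geno, causal,
                               simulation_scenario(0.5, 0.3, n_rep = 10),
                               seed = 60 + i)
    fit_gblup(phe$y, Z = phe$line, G = G)$h2
  }, numeric(1))
  expect_lt(abs(mean(h2_hat) - 0.5), 0.15)
})
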