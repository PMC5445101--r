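#' Define a genomic feature as a marker set
#'
#' @param marker_idx integer indices into the genotype marker order.
#' @param name feature identifier.
#' @param genes optional named list mapping gene ids to marker indices (a
#'   possibly overlapping cover of the feature) for gene-level decomposition.
#' @return an object of class `feature_set`.
#' @export
feature_set <- function(marker_idx, name = "feature", genes = NULL) {
  marker_idx <- unique(as.integer(marker_idx))
  if (length(marker_idx) < 1) stop("a feature needs at least one marker")
  if (any(marker_idx < 1)) stop("marker indices must be positive")
  if (!is.null(genes)) {
    if (is.null(names(genes))) stop("genes must be a named list")
    if (any(vapply(genes, length, 1L) == 0)) stop("gene with zero markers")
  }
  structure(list(name = name, marker_idx = marker_idx, genes = genes),
            class = "feature_set")
}

feature_indices <- function(feature) {
  if (inherits(feature, "feature_set")) feature$marker_idx
  else unique(as.integer(feature))
}

#' Per-marker contributions of a set statistic
#'
#' Every set statistic in the package is the sum (up to a constant factor) of
#' per-marker terms, which is what makes a single permutation engine serve
#' all of them. The contributions are, per marker i:
#' \describe{
#'   \item{cvat}{`s_hat_i * (g_hat' w_i)`, so the feature sum is the
#'     covariance statistic `g_hat' g_hat_f`.}
#'   \item{score}{`(e_bar' w_i)^2` with `e_bar = Z' Vhat^-1 (y - X b_hat)`;
#'     the score statistic is `1/(2 m_f)` times the feature sum.}
#'   \item{sum}{`s_hat_i^2` (basis `"s2"`) or `t_i^2` (basis `"t2"`).}
#'   \item{count}{the indicator `|t_i| > t0`.}
#'   \item{mt_cvat}{`s2_hat_i * (g1_hat' w_i)` (and the transposed variant),
#'     whose feature sum is the across-trait covariance statistic.}
#' }
#'
#' @param effects a [backsolve_effects()] result.
#' @param genotypes the matching [genotype_data()].
#' @param statistic one of `"cvat"`, `"score"`, `"sum"`, `"count"`,
#'   `"mt_cvat"`.
#' @param basis for `"sum"`: `"s2"` or `"t2"`.
#' @param t0 for `"count"`: threshold on `|t|` (see [count_test()] for the
#'   p-value-cutoff interface).
#' @param second_trait_effects for `"mt_cvat"`: the `marker_effects` of the
#'   trait whose back-solved effects form the feature-side sum, while
#'   `effects` supplies the total genomic value side.
#' @return numeric vector of length `n_markers(genotypes)`.
#' @export
per_marker_contributions <- function(effects, genotypes,
                                     statistic = c("cvat", "score", "sum",
                                                   "count", "mt_cvat"),
                                     basis = c("s2", "t2"), t0 = NULL,
                                     second_trait_effects = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(effects, "marker_effects"))
  m <- n_markers(genotypes)
  if (length(effects$s_hat) != m) {
    stop("effects not aligned to the genotype marker order")
  }
  W <- genotypes$W[effects$lines_obs, , drop = FALSE]
  switch(statistic,
    cvat = effects$s_hat * drop(crossprod(W, effects$g_total)),
    score = drop(crossprod(W, effects$e_bar))^2,
    sum = {
      basis <- match.arg(basis)
      if (basis == "s2") effects$s_hat^2 else effects$t_stat^2
    },
    count = {
      if (is.null(t0)) stop("count contributions need a threshold t0")
      as.numeric(abs(effects$t_stat) > t0)
    },
    mt_cvat = {
      if (is.null(second_trait_effects)) stop("second trait effects missing")
      second_trait_effects$s_hat * drop(crossprod(W, effects$g_total))
    })
}

new_set_test_result <- function(statistic_name, observed, null, feature,
                                p_parametric = NA_real_, extra = list()) {
  structure(c(list(statistic_name = statistic_name, observed = observed,
                   feature = feature$name, m_f = length(feature$marker_idx),
                   p_empirical = null$p_empirical,
                   p_parametric = p_parametric,
                   null_mean = null$null_mean, null_var = null$null_var,
                   n_perm = null$n_perm,
                   null_samples = null$null_samples), extra),
            class = "set_test_result")
}

#' @export
print.set_test_result <- function(x, ...) {
  cat(sprintf("%s: T = %.6g (feature '%s', m_f = %d)\n", x$statistic_name,
              x$observed, x$feature, x$m_f))
  cat(sprintf("  empirical p = %.4g (%d permutations)", x$p_empirical, x$n_perm))
  if (!is.na(x$p_parametric)) cat(sprintf(", parametric p = %.4g", x$p_parametric))
  cat("\n")
  invisible(x)
}

#' Covariance association test (CVAT)
#'
#' Tests a marker set by the covariance between the total genomic value and
#' the feature genomic value, `T = g_hat' g_hat_f`, with an empirical
#' p-value under the competitive null. The result also carries the
#' decomposition `T = g_f' g_f + g_r' g_f` into the feature's own variance
#' and its covariance with the remaining markers; the two evaluation routes
#' are asserted to agree.
#'
#' @param effects a [backsolve_effects()] result.
#' @param genotypes the matching [genotype_data()].
#' @param feature a [feature_set()] or integer marker indices.
#' @param engine a [null_engine()].
#' @return a `set_test_result`; `decomposition` holds the two components.
#' @export
cvat <- function(effects, genotypes, feature, engine = null_engine()) {
  feature <- as_feature(feature)
  f <- feature$marker_idx
  contribs <- per_marker_contributions(effects, genotypes, "cvat")
  observed <- sum(contribs[f])

  W <- genotypes$W[effects$lines_obs, , drop = FALSE]
  g_f <- drop(W[, f, drop = FALSE] %*% effects$s_hat[f])
  r <- setdiff(seq_len(n_markers(genotypes)), f)
  g_r <- drop(W[, r, drop = FALSE] %*% effects$s_hat[r])
  dec <- c(ff = sum(g_f^2), rf = sum(g_r * g_f))
  if (abs(sum(dec) - observed) > 1e-6 * max(1, abs(observed))) {
    stop("CVAT decomposition routes disagree; marker alignment is broken")
  }
  null <- empirical_pvalue(observed, contribs, f, engine)
  new_set_test_result("CVAT", observed, null, feature,
                      extra = list(decomposition = dec))
}

#' SKAT-type score test for a marker set
#'
#' Quadratic-form score statistic
#' `T = 1/2 (y - X b)' V^-1 G_f V^-1 (y - X b) = 1/(2 m_f) ||W_f' e_bar||^2`
#' with `b` and `V` estimated under a null model without the feature effect.
#' The default null model is the all-marker GBLUP fit (fitted once for any
#' number of features); `null_model = "exclude_feature"` refits the null with
#' the feature's markers excluded from the relationship matrix, which is
#' exact but costs one REML fit per feature.
#'
#' @param null_fit the null-model `gblup_fit`.
#' @param genotypes the matching [genotype_data()].
#' @param feature a [feature_set()] or integer marker indices.
#' @param engine a [null_engine()].
#' @param null_model `"all_markers"` or `"exclude_feature"`.
#' @param satterthwaite also compute a parametric p-value by matching a
#'   gamma distribution to the permutation-null moments.
#' @return a `set_test_result` (with `p_parametric` when requested).
#' @export
score_test <- function(null_fit, genotypes, feature, engine = null_engine(),
                       null_model = c("all_markers", "exclude_feature"),
                       satterthwaite = TRUE) {
  null_model <- match.arg(null_model)
  feature <- as_feature(feature)
  f <- feature$marker_idx
  m <- n_markers(genotypes)
  if (null_model == "exclude_feature") {
    rest <- setdiff(seq_len(m), f)
    if (length(rest) == 0) stop("feature covers all markers: empty null GRM")
    message("refitting null model without ", length(f), " feature markers")
    G_r <- build_grm(genotypes, rest)
    null_fit <- fit_gblup(null_fit$y, X = null_fit$X,
                          Z = null_fit$lines_obs[null_fit$line_index],
                          G = G_r)
  }
  eff <- list(s_hat = numeric(m), e_bar = null_fit$e_bar,
              g_total = null_fit$g_total, lines_obs = null_fit$lines_obs)
  class(eff) <- "marker_effects"
  contribs <- per_marker_contributions(eff, genotypes, "score")
  scale <- 1 / (2 * length(f))
  observed <- sum(contribs[f]) * scale
  null <- empirical_pvalue(observed, contribs, f, engine, scale = scale)
  p_par <- if (satterthwaite) {
    satterthwaite_gamma_p(observed, null$null_mean, null$null_var)
  } else NA_real_
  new_set_test_result("Score", observed, null, feature, p_parametric = p_par)
}

#' Gamma tail probability by Satterthwaite moment matching
#'
#' Approximates the null distribution of a positive quadratic-form statistic
#' by a gamma distribution with shape `mean^2/var` and scale `var/mean`
#' matched to the null mean and variance, and returns the upper-tail
#' probability at the observed value.
#'
#' @param observed observed statistic.
#' @param null_mean,null_var first two moments of the null distribution
#'   (here: of the permutation sample).
#' @return upper-tail p-value.
#' @export
satterthwaite_gamma_p <- function(observed, null_mean, null_var) {
  if (!is.finite(null_mean) || !is.finite(null_var) ||
      null_mean <= 0 || null_var <= 0) {
    stop("moment matching requires positive null mean and variance")
  }
  shape <- null_mean^2 / null_var
  scale <- null_var / null_mean
  stats::pgamma(observed, shape = shape, scale = scale, lower.tail = FALSE)
}

#' Sum test for a marker set
#'
#' `T = sum_{i in f} s_hat_i^2` (basis `"s2"`) or `sum t_i^2` (basis
#' `"t2"`); significance only by permutation.
#'
#' @inheritParams cvat
#' @param basis `"s2"` or `"t2"`.
#' @return a `set_test_result`.
#' @export
sum_test <- function(effects, genotypes, feature, basis = c("s2", "t2"),
                     engine = null_engine()) {
  basis <- match.arg(basis)
  feature <- as_feature(feature)
  contribs <- per_marker_contributions(effects, genotypes, "sum", basis = basis)
  observed <- sum(contribs[feature$marker_idx])
  null <- empirical_pvalue(observed, contribs, feature$marker_idx, engine)
  new_set_test_result(paste0("Sum(", basis, ")"), observed, null, feature)
}

#' Count test for a marker set
#'
#' Counts the feature markers whose single-marker statistic exceeds a
#' threshold, `T = sum_{i in f} I(|t_i| > t0)`. The threshold is given either
#' as a single-marker p-value cutoff (converted through the t quantile at the
#' fit's residual degrees of freedom; defaults 0.05/0.01 are conventional) or
#' directly on the |t| scale. The parametric null treats T as hypergeometric
#' `Hyper(m, m_a, m_f)` with `m_a` the number of associated markers in the
#' null domain; an empirical permutation p-value is computed as well.
#'
#' @inheritParams cvat
#' @param p0 single-marker p-value cutoff defining "associated".
#' @param t0 alternative threshold on `|t|` (overrides `p0`).
#' @return a `set_test_result`; `p_parametric` is the hypergeometric
#'   upper-tail probability `P(X >= T)`, `m_a` and `t0` are reported.
#' @export
count_test <- function(effects, genotypes, feature, p0 = 0.05, t0 = NULL,
                       engine = null_engine()) {
  feature <- as_feature(feature)
  if (is.null(t0)) t0 <- stats::qt(1 - p0 / 2, df = effects$df_e[1])
  contribs <- per_marker_contributions(effects, genotypes, "count", t0 = t0)
  domain <- if (is.null(engine$domain)) seq_along(contribs) else engine$domain
  m <- length(domain)
  m_a <- sum(contribs[domain])
  m_f <- length(feature$marker_idx)
  observed <- sum(contribs[feature$marker_idx])
  if (m_a == 0) {
    warning("no associated markers in the null domain; parametric p = 1",
            call. = FALSE)
    p_hyper <- 1
  } else {
    p_hyper <- stats::phyper(observed - 1, m_a, m - m_a, m_f,
                             lower.tail = FALSE)
  }
  null <- empirical_pvalue(observed, contribs, feature$marker_idx, engine)
  new_set_test_result("Count", observed, null, feature,
                      p_parametric = p_hyper,
                      extra = list(m_a = m_a, t0 = t0))
}

#' Gene-level decomposition of the CVAT statistic
#'
#' Splits the feature's covariance statistic into per-gene contributions
#' `g_hat' g_hat_{f_i}`. Because gene sizes differ, each contribution is also
#' reported per SNP (divided by the gene's marker count). When the genes
#' partition the feature disjointly the contributions sum to the feature
#' statistic; overlapping genes are evaluated independently (no double-count
#' correction) and flagged.
#'
#' @param effects a [backsolve_effects()] result.
#' @param genotypes the matching [genotype_data()].
#' @param feature a [feature_set()] with its `genes` map filled.
#' @return data.frame with gene, m_gene, T_gene, T_per_snp, plus attributes
#'   `feature_T` and `overlapping`.
#' @export
cvat_decompose <- function(effects, genotypes, feature) {
  feature <- as_feature(feature)
  if (is.null(feature$genes)) stop("feature has no gene map")
  contribs <- per_marker_contributions(effects, genotypes, "cvat")
  genes <- feature$genes
  T_gene <- vapply(genes, function(idx) sum(contribs[idx]), numeric(1))
  m_gene <- vapply(genes, length, integer(1))
  all_idx <- unlist(genes, use.names = FALSE)
  overlapping <- anyDuplicated(all_idx) > 0
  out <- data.frame(gene = names(genes), m_gene = m_gene, T_gene = T_gene,
                    T_per_snp = T_gene / m_gene, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "feature_T") <- sum(contribs[feature$marker_idx])
  attr(out, "overlapping") <- overlapping
  out
}

#' Multi-trait CVAT statistics
#'
#' From a two-trait fit, computes the four covariance statistics between a
#' trait's total genomic value and a trait's feature genomic value:
#' within-trait `T_M = g1' g_f1` and `T_F = g2' g_f2`, and across-trait
#' `T_MF = g1' g_f2` and `T_FM = g2' g_f1`, each with its own competitive
#' empirical p-value.
#'
#' @param fit2 a [fit_multitrait()] result.
#' @param genotypes the matching [genotype_data()].
#' @param feature a [feature_set()] or integer marker indices.
#' @param engine a [null_engine()].
#' @return named list of four `set_test_result` objects: `CVAT_M`, `CVAT_F`,
#'   `CVAT_MF`, `CVAT_FM`.
#' @export
mt_cvat <- function(fit2, genotypes, feature, engine = null_engine()) {
  if (!inherits(fit2, "mt_gblup_fit")) stop("fit2 must be a two-trait fit")
  feature <- as_feature(feature)
  eff <- mt_backsolve_effects(fit2, genotypes)
  combos <- list(CVAT_M = c(1, 1), CVAT_F = c(2, 2),
                 CVAT_MF = c(1, 2), CVAT_FM = c(2, 1))
  out <- lapply(names(combos), function(nm) {
    tt <- combos[[nm]]
    contribs <- per_marker_contributions(
      eff[[tt[1]]], genotypes, "mt_cvat",
      second_trait_effects = eff[[tt[2]]])
    observed <- sum(contribs[feature$marker_idx])
    null <- empirical_pvalue(observed, contribs, feature$marker_idx, engine)
    new_set_test_result(nm, observed, null, feature)
  })
  names(out) <- names(combos)
  out
}

as_feature <- function(feature) {
  if (inherits(feature, "feature_set")) feature
  else feature_set(feature)
}
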