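#' Back-solve per-marker effects from a fitted GBLUP/GFBLUP model
#'
#' Recovers the marker effects implied by the predicted genomic values,
#' `s_hat = W' (W W')^- g_hat`, per genomic component, together with the
#' diagonal of their sampling (co)variance
#' `Var(s_hat) = W' (W W')^- Var(g_hat) (W W')^- W` and the resulting
#' t-statistics `t_j = s_hat_j / sqrt(Var(s_hat_j))` referred to a t
#' distribution with `df_e` residual degrees of freedom (two-sided p-values).
#' `W W' = m G`, so its pseudo-inverse reuses the relationship-matrix
#' eigendecomposition with a relative eigenvalue cutoff.
#'
#' @param fit a `gblup_fit` object (single- or multi-component). For
#'   two-trait fits use [mt_backsolve_effects()].
#' @param genotypes the [genotype_data()] object the relationship matrices
#'   were built from (same line and marker ordering).
#' @param full_var also return the full m x m covariance of `s_hat`
#'   (refused for m > 5000).
#' @return An object of class `marker_effects`: a list with a per-marker
#'   data.frame `table` (marker_id, chrom, pos, component, s_hat, var_s,
#'   t_stat, p_single), vectors `s_hat`, `var_s`, `t_stat`, `p_single`
#'   aligned to the genotype marker order, `df_e`, the per-line `g_total` and
#'   projected residual `e_bar` carried from the fit, and the line subset
#'   used.
#' @export
backsolve_effects <- function(fit, genotypes, full_var = FALSE) {
  stopifnot(inherits(fit, "gblup_fit"))
  m <- n_markers(genotypes)
  n_comp <- ncol(fit$g_hat)
  subsets <- marker_subsets(fit, m)
  W <- genotypes$W[fit$lines_obs, , drop = FALSE]
  if (nrow(W) != fit$n_lines) stop("fit and genotypes refer to different lines")

  s_hat <- numeric(m)
  var_s <- numeric(m)
  comp_of <- integer(m)
  Svar_full <- if (full_var) matrix(NA_real_, m, m) else NULL
  if (full_var && m > 5000) stop("full covariance refused for m > 5000")

  for (k in seq_len(n_comp)) {
    idx <- subsets[[k]]
    Wk <- W[, idx, drop = FALSE]
    mk <- length(idx)
    Gk <- fit$G[[k]]
    # sanity: G must match W W'/m on the fitted lines
    if (max(abs(Gk - tcrossprod(Wk) / mk)) > 1e-6 * max(1, max(abs(Gk)))) {
      stop("marker order/subset mismatch between fit component ", k,
           " and genotypes")
    }
    pinv <- grm_pseudo_inverse(Gk)
    WWinv <- pinv$inv / mk            # (W_k W_k')^-
    a <- drop(WWinv %*% fit$g_hat[, k])
    s_hat[idx] <- drop(crossprod(Wk, a))
    M <- WWinv %*% fit$var_ghat[[k]] %*% WWinv
    var_s[idx] <- pmax(colSums(Wk * (M %*% Wk)), 0)
    comp_of[idx] <- k
    if (full_var) Svar_full[idx, idx] <- crossprod(Wk, M %*% Wk)
  }

  eff <- structure(list(
    s_hat = s_hat, var_s = var_s, t_stat = NULL, p_single = NULL,
    component = comp_of, df_e = fit$df_e,
    g_total = fit$g_total, g_hat = fit$g_hat, e_bar = fit$e_bar,
    lines_obs = fit$lines_obs, marker_id = genotypes$marker_ids,
    chrom = genotypes$chrom, pos = genotypes$pos,
    var_s_full = Svar_full), class = "marker_effects")
  marker_t_stats(eff)
}

#' Single-marker t-statistics and p-values
#'
#' Fills the `t_stat` and `p_single` fields of a [backsolve_effects()]
#' result: `t_j = s_hat_j / sqrt(Var(s_hat_j))` with a two-sided p-value from
#' the t distribution on `df_e` degrees of freedom. Markers whose effect
#' variance falls below `var_floor` are flagged and assigned `t = 0, p = 1`.
#'
#' @param effects a `marker_effects` object.
#' @param var_floor variance floor applied before division.
#' @return the `marker_effects` object with `t_stat`, `p_single` and
#'   `flagged` filled, plus the assembled per-marker `table`.
#' @export
marker_t_stats <- function(effects, var_floor = 1e-12) {
  stopifnot(inherits(effects, "marker_effects"))
  if (is.null(effects$df_e) || any(effects$df_e <= 0)) {
    stop("df_e must be positive")
  }
  flagged <- effects$var_s < var_floor
  t_stat <- ifelse(flagged, 0, effects$s_hat / sqrt(pmax(effects$var_s, var_floor)))
  p <- ifelse(flagged, 1, 2 * stats::pt(-abs(t_stat), df = effects$df_e[1]))
  effects$t_stat <- t_stat
  effects$p_single <- p
  effects$flagged <- flagged
  effects$table <- data.frame(
    marker_id = effects$marker_id, chrom = effects$chrom, pos = effects$pos,
    component = effects$component, s_hat = effects$s_hat,
    var_s = effects$var_s, t_stat = t_stat, p_single = p,
    stringsAsFactors = FALSE)
  effects
}

#' Back-solve per-trait marker effects from a two-trait fit
#'
#' @param fit a `mt_gblup_fit` object.
#' @param genotypes the [genotype_data()] object behind the fit's `G`.
#' @return list with elements `t1` and `t2`, each a `marker_effects` object
#'   holding that trait's back-solved effects and the trait's predicted
#'   genomic values; across-trait statistics are formed by [mt_cvat()].
#' @export
mt_backsolve_effects <- function(fit, genotypes) {
  stopifnot(inherits(fit, "mt_gblup_fit"))
  W <- genotypes$W
  m <- n_markers(genotypes)
  Gm <- fit$G
  if (max(abs(Gm - tcrossprod(W) / m)) > 1e-6 * max(1, max(abs(Gm)))) {
    stop("marker order mismatch between fit and genotypes")
  }
  pinv <- grm_pseudo_inverse(Gm)
  WWinv <- pinv$inv / m
  out <- lapply(1:2, function(t) {
    a <- drop(WWinv %*% fit$g_hat[, t])
    s <- drop(crossprod(W, a))
    structure(list(
      s_hat = s, var_s = rep(NA_real_, m), t_stat = NULL, p_single = NULL,
      component = rep(1L, m), df_e = unname(fit$df_e[t]),
      g_total = fit$g_hat[, t], g_hat = fit$g_hat[, t, drop = FALSE],
      e_bar = fit$e_bar[, t], lines_obs = seq_len(nrow(Gm)),
      marker_id = genotypes$marker_ids, chrom = genotypes$chrom,
      pos = genotypes$pos, var_s_full = NULL), class = "marker_effects")
  })
  names(out) <- c("t1", "t2")
  out
}

#' @export
print.marker_effects <- function(x, ...) {
  cat("marker_effects:", length(x$s_hat), "markers, df_e =",
      sprintf("%.1f", x$df_e[1]), "\n")
  invisible(x)
}

marker_subsets <- function(fit, m) {
  lapply(seq_along(fit$G_input), function(k) {
    g <- fit$G_input[[k]]
    if (inherits(g, "grm")) g$marker_subset else seq_len(m)
  })
}
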