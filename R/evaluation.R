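#' F1 score from detection counts
#'
#' Harmonic mean of precision `p = TP/(TP+FP)` and recall `r = TP/(TP+FN)`:
#' `F1 = 2 p r / (p + r)`, defined as 0 when `p + r = 0`.
#'
#' @param TP,FP,FN non-negative counts.
#' @return scalar in [0, 1].
#' @export
f1_score <- function(TP, FP, FN) {
  if (any(c(TP, FP, FN) < 0)) stop("counts must be non-negative")
  if (TP == 0) return(0)
  p <- TP / (TP + FP)
  r <- TP / (TP + FN)
  2 * p * r / (p + r)
}

#' Classify set-test detections and compute power metrics
#'
#' Turns a [run_scenario_grid()] results table into detection counts and the
#' F1 power measure at a p-value cutoff: causal features with
#' `p < alpha` are true positives (otherwise false negatives), null sets with
#' `p < alpha` are false positives (otherwise true negatives). Two summaries
#' are available: per dilution level (power as a function of dilution), or
#' with each data set's causal p-values first averaged over the dilution
#' range (a single power value per scenario cell).
#'
#' @param results data.frame from [run_scenario_grid()] (one scenario cell;
#'   several statistics allowed).
#' @param alpha p-value cutoff for a positive detection.
#' @param by `"dilution"` or `"average"`.
#' @return data.frame with one row per (statistic, dilution level) or per
#'   statistic: TP, FP, FN, TN, precision, recall, F1.
#' @export
classify_detections <- function(results, alpha = 0.05,
                                by = c("dilution", "average")) {
  by <- match.arg(by)
  if (!any(results$feature_type == "null")) {
    stop("no null sets in results: precision undefined")
  }
  stats_ <- unique(results$statistic)
  out <- list()
  for (st in stats_) {
    r <- results[results$statistic == st, ]
    null_p <- r$p_empirical[r$feature_type == "null"]
    FP <- sum(null_p < alpha)
    TN <- sum(null_p >= alpha)
    ca <- r[r$feature_type == "causal", ]
    if (by == "average") {
      pbar <- tapply(ca$p_empirical, ca$dataset, mean)
      TP <- sum(pbar < alpha)
      FN <- sum(pbar >= alpha)
      out[[length(out) + 1]] <- data.frame(
        statistic = st, dilution = NA, TP = TP, FP = FP, FN = FN, TN = TN,
        precision = ifelse(TP + FP > 0, TP / (TP + FP), NA),
        recall = TP / (TP + FN), F1 = f1_score(TP, FP, FN),
        stringsAsFactors = FALSE)
    } else {
      for (d in sort(unique(ca$dilution))) {
        cp <- ca$p_empirical[ca$dilution == d]
        TP <- sum(cp < alpha)
        FN <- sum(cp >= alpha)
        out[[length(out) + 1]] <- data.frame(
          statistic = st, dilution = d, TP = TP, FP = FP, FN = FN, TN = TN,
          precision = ifelse(TP + FP > 0, TP / (TP + FP), NA),
          recall = TP / (TP + FN), F1 = f1_score(TP, FP, FN),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Cross-validated predictive ability of a GFBLUP model
#'
#' Fits the two-component model (feature + remaining markers) on repeated
#' random 90/10 line-level splits; per split, the total genomic values of the
#' validation lines are predicted from the training phenotypes, and the
#' Spearman correlation with the total genomic values predicted from the
#' full data (validation phenotypes observed) is recorded. The predictive
#' ability is the mean correlation over splits. A conventional alternative —
#' correlating predictions with observed line-mean phenotypes — is available
#' via `against = "phenotype"`.
#'
#' @param y phenotype vector.
#' @param Z line assignment for `y` (see [fit_gblup()]).
#' @param genotypes a [genotype_data()] object.
#' @param feature a [feature_set()] or integer marker indices.
#' @param n_folds number of random splits.
#' @param train_frac fraction of lines in each training set.
#' @param against `"full_fit"` (default) or `"phenotype"`.
#' @param seed integer seed controlling the splits.
#' @param control a [reml_control()] list.
#' @return list with `pa` (mean Spearman correlation), `fold_cor`,
#'   `n_failed` (splits skipped for non-convergence or errors).
#' @export
gfblup_cv_predictive_ability <- function(y, Z, genotypes, feature,
                                         n_folds = 50, train_frac = 0.9,
                                         against = c("full_fit", "phenotype"),
                                         seed = 1, control = reml_control()) {
  against <- match.arg(against)
  f_idx <- feature_indices(feature)
  m <- n_markers(genotypes)
  rest <- setdiff(seq_len(m), f_idx)
  if (length(rest) == 0) stop("feature covers all markers")
  G_f <- build_grm(genotypes, f_idx)
  G_r <- build_grm(genotypes, rest)
  G_list <- list(f = G_f, r = G_r)

  li <- line_index(Z, length(y), n_lines(genotypes), G_f$G)
  n <- n_lines(genotypes)
  ybar <- tapply(y, li, mean)

  full_fit <- fit_gfblup(y, Z = li, G_list = G_list, control = control)
  g_full <- full_fit$g_total
  full_lines <- full_fit$lines_obs

  set.seed(seed)
  n_train <- round(train_frac * length(full_lines))
  fold_cor <- rep(NA_real_, n_folds)
  for (k in seq_len(n_folds)) {
    train_lines <- sort(sample(full_lines, n_train))
    val_lines <- setdiff(full_lines, train_lines)
    obs <- li %in% train_lines
    fit_k <- tryCatch(
      suppressWarnings(fit_gfblup(y[obs], Z = li[obs], G_list = G_list,
                                  control = control)),
      error = function(e) NULL)
    if (is.null(fit_k)) next
    pred <- drop(
      fit_k$vc$sigma_g2[1] * G_f$G[val_lines, fit_k$lines_obs] %*% fit_k$e_bar +
      fit_k$vc$sigma_g2[2] * G_r$G[val_lines, fit_k$lines_obs] %*% fit_k$e_bar)
    target <- if (against == "full_fit") {
      g_full[match(val_lines, full_lines)]
    } else {
      ybar[as.character(val_lines)]
    }
    fold_cor[k] <- stats::cor(pred, target, method = "spearman")
  }
  list(pa = mean(fold_cor, na.rm = TRUE), fold_cor = fold_cor,
       n_failed = sum(is.na(fold_cor)))
}

#' Rank correlation between set-test significance and predictive ability
#'
#' Spearman correlation between `-log(p)` of a set statistic and the
#' cross-validated predictive ability of the matching feature models.
#'
#' @param p_values named or plain numeric vector of empirical p-values, one
#'   per feature.
#' @param pa numeric vector of predictive abilities aligned to `p_values`
#'   (matched by names when both are named).
#' @return Spearman rank correlation.
#' @export
significance_vs_pa <- function(p_values, pa) {
  if (!is.null(names(p_values)) && !is.null(names(pa))) {
    shared <- intersect(names(p_values), names(pa))
    p_values <- p_values[shared]
    pa <- pa[shared]
  }
  if (length(p_values) != length(pa)) stop("inputs are not aligned")
  if (length(p_values) < 3) stop("need at least 3 shared features")
  stats::cor(-log(p_values), pa, method = "spearman")
}
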