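#' Build a genomic relationship matrix
#'
#' Computes `G = W W' / m` from the centered and scaled genotype matrix `W`,
#' optionally restricted to a marker subset. Because the columns of `W` are
#' mean-centered over lines, the rows of `G` sum to zero and `G` is rank
#' deficient; downstream inverses use an eigenvalue-thresholded pseudo-inverse
#' (see [grm_pseudo_inverse()]).
#'
#' @param genotypes a [genotype_data()] object.
#' @param marker_subset optional integer indices of the markers to use;
#'   default all markers.
#' @return An object of class `grm`: list with `G` (n x n), `m_used`,
#'   `marker_subset`.
#' @export
build_grm <- function(genotypes, marker_subset = NULL) {
  m <- n_markers(genotypes)
  if (is.null(marker_subset)) marker_subset <- seq_len(m)
  marker_subset <- sort(unique(as.integer(marker_subset)))
  if (length(marker_subset) == 0) stop("marker subset is empty")
  if (any(marker_subset < 1) || any(marker_subset > m)) {
    stop("marker subset indices out of range")
  }
  Ws <- genotypes$W[, marker_subset, drop = FALSE]
  G <- tcrossprod(Ws) / length(marker_subset)
  dimnames(G) <- list(genotypes$line_ids, genotypes$line_ids)
  structure(list(G = G, m_used = length(marker_subset),
                 marker_subset = marker_subset),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", nrow(x$G), "lines, built from", x$m_used, "markers\n")
  invisible(x)
}

as_grm_matrix <- function(G) {
  if (inherits(G, "grm")) G$G else as.matrix(G)
}

#' Eigen-based pseudo-inverse of a genomic relationship matrix
#'
#' Relationship matrices built from centered genotypes are singular, so every
#' inverse of `G` or `W W'` is a generalized inverse. Eigenvalues below
#' `rel_tol * max(eigenvalue)` are treated as zero.
#'
#' @param G a `grm` object or symmetric matrix.
#' @param rel_tol relative eigenvalue cutoff.
#' @return list with `inv` (the pseudo-inverse), `vectors`, `values`, `rank`.
#' @export
grm_pseudo_inverse <- function(G, rel_tol = 1e-8) {
  Gm <- as_grm_matrix(G)
  eg <- eigen(Gm, symmetric = TRUE)
  cutoff <- rel_tol * max(abs(eg$values))
  pos <- eg$values > cutoff
  d_inv <- ifelse(pos, 1 / eg$values, 0)
  inv <- eg$vectors %*% (d_inv * t(eg$vectors))
  list(inv = inv, vectors = eg$vectors, values = eg$values, rank = sum(pos))
}
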