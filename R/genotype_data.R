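#' Construct a genotype data object
#'
#' Wraps an allele-count matrix for a panel of lines together with the marker
#' map, minor-allele frequencies and the centered/scaled genotype matrix used
#' throughout GBLUP. Columns counting the major allele are recoded so that
#' every column counts the minor allele, monomorphic markers and markers below
#' the minor-allele-frequency threshold are removed, and markers are sorted by
#' chromosome (in the order given by `chrom_order`) and position. The i-th
#' column of the scaled matrix is `(a_i - 2 p_i) / sqrt(2 p_i (1 - p_i))`.
#'
#' @param A numeric matrix of allele counts in 0/1/2, lines in rows, markers
#'   in columns. Row and column names are used as line and marker identifiers
#'   when present.
#' @param chrom character vector of per-marker chromosome labels.
#' @param pos numeric vector of per-marker base-pair positions.
#' @param maf_min minimum minor allele frequency retained after QC.
#' @param chrom_order explicit chromosome ordering for the circular genome;
#'   defaults to order of first appearance.
#' @param line_ids,marker_ids optional identifier vectors overriding dimnames.
#'
#' @return An object of class `genotype_data`: a list with elements
#'   `line_ids`, `marker_ids`, `chrom`, `pos`, `A`, `p` (minor allele
#'   frequency), `W` (centered and scaled matrix) and `chrom_order`.
#' @export
genotype_data <- function(A, chrom = NULL, pos = NULL, maf_min = 0,
                          chrom_order = NULL, line_ids = NULL,
                          marker_ids = NULL) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  n <- nrow(A)
  m <- ncol(A)
  if (is.null(line_ids)) {
    line_ids <- if (!is.null(rownames(A))) rownames(A) else paste0("line", seq_len(n))
  }
  if (is.null(marker_ids)) {
    marker_ids <- if (!is.null(colnames(A))) colnames(A) else paste0("mrk", seq_len(m))
  }
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m)
  chrom <- as.character(chrom)
  stopifnot(length(chrom) == m, length(pos) == m, length(line_ids) == n,
            length(marker_ids) == m)
  if (any(A < 0 | A > 2, na.rm = TRUE)) {
    stop("allele counts must lie in [0, 2]")
  }
  if (anyNA(A)) stop("missing genotypes must be imputed before construction")

  # fold to minor-allele coding
  freq <- colMeans(A) / 2
  flip <- freq > 0.5
  if (any(flip)) {
    A[, flip] <- 2 - A[, flip]
    freq[flip] <- 1 - freq[flip]
  }

  keep <- freq >= max(maf_min, .Machine$double.eps) & freq > 0
  if (!any(keep)) stop("no markers survive the MAF filter")

  if (is.null(chrom_order)) chrom_order <- unique(chrom[keep])
  bad <- setdiff(unique(chrom[keep]), chrom_order)
  if (length(bad) > 0) {
    stop("chromosomes absent from chrom_order: ", paste(bad, collapse = ", "))
  }
  ord <- which(keep)[order(match(chrom[keep], chrom_order), pos[keep])]

  A <- A[, ord, drop = FALSE]
  p <- freq[ord]
  W <- sweep(A, 2, 2 * p, "-")
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
  dimnames(A) <- dimnames(W) <- list(line_ids, marker_ids[ord])

  structure(list(line_ids = line_ids, marker_ids = marker_ids[ord],
                 chrom = chrom[ord], pos = pos[ord], A = A, p = p, W = W,
                 chrom_order = chrom_order),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat("genotype_data:", length(x$line_ids), "lines x", length(x$marker_ids),
      "markers on", length(unique(x$chrom)), "chromosome(s)\n")
  cat("  MAF range:", sprintf("%.3f-%.3f", min(x$p), max(x$p)), "\n")
  invisible(x)
}

#' Number of lines / markers
#' @param geno a `genotype_data` object.
#' @return integer count.
#' @export
n_lines <- function(geno) length(geno$line_ids)

#' @rdname n_lines
#' @export
n_markers <- function(geno) length(geno$marker_ids)

#' Subset the marker dimension of a genotype object
#'
#' @param geno a `genotype_data` object.
#' @param idx integer marker indices (original order retained).
#' @return a `genotype_data` object restricted to `idx`.
#' @export
subset_markers <- function(geno, idx) {
  idx <- sort(unique(as.integer(idx)))
  stopifnot(length(idx) >= 1, all(idx >= 1), all(idx <= n_markers(geno)))
  structure(list(line_ids = geno$line_ids, marker_ids = geno$marker_ids[idx],
                 chrom = geno$chrom[idx], pos = geno$pos[idx],
                 A = geno$A[, idx, drop = FALSE], p = geno$p[idx],
                 W = geno$W[, idx, drop = FALSE],
                 chrom_order = geno$chrom_order),
            class = "genotype_data")
}
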