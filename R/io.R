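#' Genotype QC configuration
#'
#' Thresholds applied when reading genotypes: minimum minor allele frequency,
#' minimum Phred-scaled variant quality (VCF QUAL) and minimum genotype call
#' rate per marker.
#'
#' @param maf_min minimum minor allele frequency.
#' @param qual_min variant QUAL must be strictly greater than this.
#' @param callrate_min minimum fraction of called genotypes per marker.
#' @return a named list of class `qc_config`.
#' @export
qc_config <- function(maf_min = 0.05, qual_min = 500, callrate_min = 0.8) {
  stopifnot(maf_min >= 0, maf_min < 0.5, qual_min >= 0,
            callrate_min >= 0, callrate_min <= 1)
  structure(list(maf_min = maf_min, qual_min = qual_min,
                 callrate_min = callrate_min), class = "qc_config")
}

#' Read genotypes from VCF or a tab-separated allele-count matrix
#'
#' VCF input keeps biallelic SNPs only (dropped records are counted in a
#' message), applies the QUAL and call-rate filters, converts genotype calls
#' to alternate-allele counts, imputes missing genotypes to twice the allele
#' frequency (`2 p_i`), and applies the MAF filter. TSV input expects lines
#' in rows and a header of marker ids, with an accompanying marker map file
#' (columns `marker_id`, `chrom`, `pos`).
#'
#' @param path genotype file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param map marker map path or data.frame (TSV input only).
#' @param qc a [qc_config()].
#' @param chrom_order optional explicit chromosome ordering.
#' @return a [genotype_data()] object.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv"), map = NULL,
                           qc = qc_config(), chrom_order = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "vcf") read_genotypes_vcf(path, qc, chrom_order)
  else read_genotypes_tsv(path, map, qc, chrom_order)
}

read_genotypes_vcf <- function(path, qc, chrom_order) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")

  snp <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 & !grepl(",", fix$ALT) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  pass_qual <- !is.na(qual) & qual > qc$qual_min
  dropped_nonsnp <- sum(!snp)
  if (dropped_nonsnp > 0) {
    message(dropped_nonsnp, " non-biallelic-SNP record(s) dropped")
  }

  counts <- matrix(NA_real_, nrow(gt), ncol(gt))
  counts[gt %in% c("0/0", "0|0")] <- 0
  counts[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
  counts[gt %in% c("1/1", "1|1")] <- 2
  callrate <- rowMeans(!is.na(counts))

  keep <- snp & pass_qual & callrate >= qc$callrate_min
  if (!any(keep)) stop("all markers removed by QC")
  counts <- counts[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  # mean imputation on the allele-count scale (flagged)
  n_missing <- sum(is.na(counts))
  if (n_missing > 0) {
    message(n_missing, " missing genotype(s) imputed to 2p")
    for (i in which(rowSums(is.na(counts)) > 0)) {
      counts[i, is.na(counts[i, ])] <- mean(counts[i, ], na.rm = TRUE)
    }
  }
  A <- t(counts)
  rownames(A) <- colnames(gt)
  colnames(A) <- ifelse(is.na(fix$ID) | fix$ID == ".",
                        paste0(fix$CHROM, "_", fix$POS), fix$ID)
  genotype_data(A, chrom = fix$CHROM, pos = as.numeric(fix$POS),
                maf_min = qc$maf_min, chrom_order = chrom_order)
}

read_genotypes_tsv <- function(path, map, qc, chrom_order) {
  A <- as.matrix(data.table::fread(path, header = TRUE), rownames = 1)
  chrom <- NULL
  pos <- NULL
  if (!is.null(map)) {
    mp <- if (is.character(map)) data.table::fread(map) else map
    mp <- as.data.frame(mp)
    idx <- match(colnames(A), mp$marker_id)
    if (anyNA(idx)) stop("markers missing from the map file")
    chrom <- as.character(mp$chrom[idx])
    pos <- as.numeric(mp$pos[idx])
  }
  genotype_data(A, chrom = chrom, pos = pos, maf_min = qc$maf_min,
                chrom_order = chrom_order)
}

#' Write genotypes as TSV matrix + marker map
#'
#' @param geno a [genotype_data()] object.
#' @param prefix output path prefix; writes `<prefix>.geno.tsv` and
#'   `<prefix>.map.tsv`.
#' @return invisibly, the two file paths.
#' @export
write_genotypes_tsv <- function(geno, prefix) {
  gpath <- paste0(prefix, ".geno.tsv")
  mpath <- paste0(prefix, ".map.tsv")
  dt <- data.table::data.table(line_id = geno$line_ids)
  dt <- cbind(dt, data.table::as.data.table(geno$A))
  data.table::fwrite(dt, gpath, sep = "\t")
  data.table::fwrite(data.table::data.table(
    marker_id = geno$marker_ids, chrom = geno$chrom, pos = geno$pos),
    mpath, sep = "\t")
  invisible(c(gpath, mpath))
}

#' Read a phenotype table
#'
#' Tab-separated with at least columns `line_id` and `value`; `trait`,
#' `replicate` and covariate columns are carried through.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  ph <- as.data.frame(data.table::fread(path))
  if (!all(c("line_id", "value") %in% colnames(ph))) {
    stop("phenotype table needs 'line_id' and 'value' columns")
  }
  ph
}

#' Read / write GMT gene-set files
#'
#' @param path GMT file (set name, description, tab-separated member ids).
#' @return `read_gmt`: named list of member-id vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param sets named list of member-id vectors.
#' @param description optional per-set description column.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Map markers to genes and gene sets
#'
#' Builds a feature catalog from gene intervals (GFF3, 1-based inclusive, or
#' BED, 0-based half-open; both read through `rtracklayer`, which normalises
#' to 1-based inclusive ranges) and optional GMT gene sets. A marker belongs
#' to a gene when its position lies within the gene's interval; a set's
#' markers are the union over its member genes; sets with fewer than
#' `min_genes` member genes are dropped.
#'
#' @param genotypes a [genotype_data()] object.
#' @param gene_intervals GFF3/BED path or a `GRanges` with gene names.
#' @param gene_sets GMT path or named list of gene-id vectors (optional).
#' @param min_genes minimum member genes per retained set.
#' @param feature_type GFF3 feature type to keep (default `"gene"`).
#' @return an object of class `feature_catalog`: list with `genes` (gene ->
#'   marker indices), `sets` (set -> gene ids), `set_markers` (set -> marker
#'   indices), `genic` (sorted union of all gene-mapped markers).
#' @export
map_markers_to_features <- function(genotypes, gene_intervals,
                                    gene_sets = NULL, min_genes = 10,
                                    feature_type = "gene") {
  gr <- gene_granges(gene_intervals, feature_type)
  marker_gr <- GenomicRanges::GRanges(
    seqnames = genotypes$chrom,
    ranges = IRanges::IRanges(start = genotypes$pos, width = 1))

  shared <- intersect(unique(genotypes$chrom),
                      as.character(unique(GenomicRanges::seqnames(gr))))
  if (length(shared) == 0) {
    stop("no shared chromosome names between genotypes (",
         paste(unique(genotypes$chrom), collapse = ","), ") and annotation (",
         paste(unique(as.character(GenomicRanges::seqnames(gr))),
               collapse = ","), ")")
  }

  hits <- GenomicRanges::findOverlaps(marker_gr, gr)
  gene_names <- names(gr)[S4Vectors::subjectHits(hits)]
  genes <- split(S4Vectors::queryHits(hits), gene_names)
  genes <- lapply(genes, function(v) sort(unique(v)))

  sets <- NULL
  set_markers <- NULL
  if (!is.null(gene_sets)) {
    if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
    keep <- vapply(gene_sets, function(g) length(unique(g)) >= min_genes,
                   logical(1))
    sets <- gene_sets[keep]
    set_markers <- lapply(sets, function(gids) {
      sort(unique(unlist(genes[intersect(gids, names(genes))],
                         use.names = FALSE)))
    })
  }
  structure(list(genes = genes, sets = sets, set_markers = set_markers,
                 genic = sort(unique(unlist(genes, use.names = FALSE)))),
            class = "feature_catalog")
}

gene_granges <- function(gene_intervals, feature_type) {
  if (methods::is(gene_intervals, "GRanges")) {
    gr <- gene_intervals
    if (is.null(names(gr))) stop("GRanges gene intervals need names")
    return(gr)
  }
  gr <- rtracklayer::import(gene_intervals)
  if (grepl("\\.gff3?(\\.gz)?$", gene_intervals)) {
    if ("type" %in% colnames(S4Vectors::mcols(gr))) {
      gr <- gr[as.character(gr$type) == feature_type]
    }
    nm <- if ("ID" %in% colnames(S4Vectors::mcols(gr))) gr$ID else gr$Name
    names(gr) <- as.character(nm)
  } else {
    names(gr) <- gr$name
  }
  if (any(is.na(names(gr)))) stop("gene intervals with missing names")
  gr
}

#' Extract a named set from a feature catalog as a feature_set
#'
#' @param catalog a [map_markers_to_features()] result.
#' @param set_name name of a gene set in the catalog.
#' @return a [feature_set()] carrying the gene-level map for
#'   [cvat_decompose()].
#' @export
catalog_feature <- function(catalog, set_name) {
  if (!set_name %in% names(catalog$set_markers)) {
    stop("unknown set: ", set_name)
  }
  gids <- intersect(catalog$sets[[set_name]], names(catalog$genes))
  feature_set(catalog$set_markers[[set_name]], name = set_name,
              genes = catalog$genes[gids])
}

#' Write variance components and genomic values of a fit
#'
#' @param fit a `gblup_fit`.
#' @param prefix output prefix; writes `<prefix>.vc.tsv` and
#'   `<prefix>.ghat.tsv`.
#' @return invisibly, the file paths.
#' @export
write_fit <- function(fit, prefix) {
  vc <- data.table::data.table(
    component = c(names(fit$vc$sigma_g2), "residual"),
    variance = c(fit$vc$sigma_g2, fit$vc$sigma_e2))
  data.table::fwrite(vc, paste0(prefix, ".vc.tsv"), sep = "\t")
  gh <- data.table::data.table(line_id = fit$line_ids)
  gh <- cbind(gh, data.table::as.data.table(fit$g_hat))
  data.table::fwrite(gh, paste0(prefix, ".ghat.tsv"), sep = "\t")
  invisible(paste0(prefix, c(".vc.tsv", ".ghat.tsv")))
}

#' Write set-test results as TSV
#'
#' @param results a `set_test_result`, a list of them, or a data.frame from
#'   [run_scenario_grid()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_set_test_results <- function(results, path) {
  if (inherits(results, "set_test_result")) results <- list(results)
  if (is.data.frame(results)) {
    data.table::fwrite(results, path, sep = "\t")
    return(invisible(path))
  }
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(feature = r$feature, statistic = r$statistic_name,
               observed = r$observed, m_f = r$m_f, n_perm = r$n_perm,
               p_empirical = r$p_empirical, p_parametric = r$p_parametric,
               stringsAsFactors = FALSE)
  }))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
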