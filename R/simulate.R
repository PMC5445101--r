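#' Simulate genotypes for a panel of inbred (or outbred) lines
#'
#' Generates DGRP-like genotype data: fully inbred lines carry homozygous
#' allele counts (0/2 only), markers are organised in haplotype blocks with
#' strong within-block and no between-block linkage disequilibrium, and minor
#' allele frequencies below `maf_min` are removed, mirroring standard panel
#' QC. Within a block each line copies one of `n_founders` founder
#' haplotypes with a small per-marker flip probability, which generates
#' realistic block LD without a coalescent simulation.
#'
#' @param n_lines number of lines.
#' @param m number of markers returned (after the MAF filter).
#' @param n_chrom number of chromosomes the markers are spread over.
#' @param block_len markers per haplotype block.
#' @param maf_range range the target minor allele frequencies are drawn from.
#' @param maf_min post-hoc minor-allele-frequency filter.
#' @param inbred homozygous lines (allele counts 0/2) if `TRUE`, otherwise
#'   two independent haplotypes per line (0/1/2).
#' @param n_founders founder haplotypes per block.
#' @param mut_rate per-marker copy error probability.
#' @param rho latent autocorrelation of founder alleles along a block;
#'   controls how fast linkage disequilibrium decays with distance.
#' @param seed optional integer seed.
#' @return a [genotype_data()] object with `m` markers.
#' @export
simulate_genotypes <- function(n_lines = 200, m = 20000, n_chrom = 5,
                               block_len = 50, maf_range = c(0.05, 0.5),
                               maf_min = 0.05, inbred = TRUE, n_founders = 8,
                               mut_rate = 0.02, rho = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (maf_range[2] <= maf_range[1]) stop("degenerate maf_range")
  if (m < 10 * block_len) stop("m must be at least 10 blocks")

  sim_block <- function() {
    p <- stats::runif(block_len, maf_range[1], maf_range[2])
    # founder haplotypes from a latent AR(1) Gaussian copula: marginally
    # Bernoulli(p_j), with allele correlation decaying along the block
    Z <- matrix(stats::rnorm(n_founders * block_len), n_founders, block_len)
    for (j in 2:block_len) {
      Z[, j] <- rho * Z[, j - 1] + sqrt(1 - rho^2) * Z[, j]
    }
    H <- 1L * (Z < matrix(stats::qnorm(p), n_founders, block_len, byrow = TRUE))
    # keep every marker polymorphic in the founder pool
    mono <- colSums(H) %in% c(0, n_founders)
    for (j in which(mono)) H[sample.int(n_founders, 1), j] <- 1 - H[1, j]
    draw_hap <- function() {
      hap <- H[sample.int(n_founders, n_lines, replace = TRUE), , drop = FALSE]
      flip <- matrix(stats::runif(n_lines * block_len) < mut_rate,
                     n_lines, block_len)
      (hap + flip) %% 2
    }
    if (inbred) 2 * draw_hap() else draw_hap() + draw_hap()
  }

  blocks <- list()
  kept <- 0
  while (kept < m) {
    need <- ceiling((m - kept) * 1.15 / block_len) + 1
    new <- lapply(seq_len(need), function(i) sim_block())
    A_new <- do.call(cbind, new)
    freq <- colMeans(A_new) / 2
    maf <- pmin(freq, 1 - freq)
    blocks <- c(blocks, list(A_new[, maf >= maf_min, drop = FALSE]))
    kept <- kept + sum(maf >= maf_min)
  }
  A <- do.call(cbind, blocks)[, seq_len(m), drop = FALSE]

  per_chrom <- ceiling(m / n_chrom)
  chrom <- paste0("chr", rep(seq_len(n_chrom), each = per_chrom))[seq_len(m)]
  pos <- as.numeric(sequence(rle(chrom)$lengths) * 1000L)
  rownames(A) <- sprintf("line%03d", seq_len(n_lines))
  colnames(A) <- sprintf("m%06d", seq_len(m))
  genotype_data(A, chrom = chrom, pos = pos, maf_min = 0,
                chrom_order = paste0("chr", seq_len(n_chrom)))
}

#' Select causal marker sets and null (non-causal) sets
#'
#' Splits 1,000 causal markers (by default) into a feature-causal subset C1
#' of 100 markers and a background subset C2 of 900 markers, plus a
#' collection of non-causal sets used to measure false-positive rates. Under
#' the `random` model C1 and C2 are drawn anywhere in the genome; under the
#' `cluster` model C1 is drawn as `n_c1 / n_regions` markers from each of
#' `n_regions` non-overlapping regions of `region_size` consecutive markers.
#' C1, C2 and the null sets are mutually disjoint.
#'
#' @param genotypes a [genotype_data()] object.
#' @param causal_model `"random"` or `"cluster"`.
#' @param n_c1,n_c2 sizes of the feature-causal and background-causal sets.
#' @param null_set_sizes sizes of the non-causal sets.
#' @param n_regions,region_size cluster-model geometry.
#' @param seed optional integer seed.
#' @return an object of class `causal_config`: list with `C1`, `C2`,
#'   `null_sets` (named list), `causal_model`, `regions` (cluster model).
#' @export
select_causal_sets <- function(genotypes,
                               causal_model = c("random", "cluster"),
                               n_c1 = 100, n_c2 = 900,
                               null_set_sizes = rep(c(100, 250, 500, 1000, 2000), 2),
                               n_regions = 20, region_size = 50,
                               seed = NULL) {
  causal_model <- match.arg(causal_model)
  if (!is.null(seed)) set.seed(seed)
  m <- n_markers(genotypes)
  need <- n_c1 + n_c2 + sum(null_set_sizes)
  if (need > m) stop("insufficient markers: need ", need, ", have ", m)

  regions <- NULL
  if (causal_model == "cluster") {
    if (n_c1 %% n_regions != 0) stop("n_c1 must be a multiple of n_regions")
    per_region <- n_c1 / n_regions
    repeat {
      starts <- sort(sample.int(m - region_size + 1, n_regions))
      if (all(diff(starts) >= region_size)) break
    }
    regions <- lapply(starts, function(s) s:(s + region_size - 1))
    C1 <- sort(unlist(lapply(regions, function(r) sort(sample(r, per_region)))))
  } else {
    C1 <- sort(sample.int(m, n_c1))
  }
  pool <- setdiff(seq_len(m), C1)
  C2 <- sort(pool[sample.int(length(pool), n_c2)])
  pool <- setdiff(pool, C2)
  null_sets <- vector("list", length(null_set_sizes))
  for (i in seq_along(null_set_sizes)) {
    pick <- pool[sample.int(length(pool), null_set_sizes[i])]
    null_sets[[i]] <- sort(pick)
    pool <- setdiff(pool, pick)
  }
  names(null_sets) <- sprintf("null%02d_%d", seq_along(null_set_sizes),
                              null_set_sizes)
  structure(list(C1 = C1, C2 = C2, null_sets = null_sets,
                 causal_model = causal_model, regions = regions),
            class = "causal_config")
}

#' Simulation scenario parameters
#'
#' Encodes one cell of the simulation design: the genomic heritability `h2`,
#' the proportion `hf2` of genomic variance explained by the feature-causal
#' set C1, the number of phenotypic replicates per line, the causal model and
#' the dilution level. The generating variance components follow from the
#' total phenotypic variance `sigma_P2`:
#' `sigma_g1^2 = h2 * hf2 * sigma_P2`,
#' `sigma_g2^2 = h2 * (1 - hf2) * sigma_P2`,
#' `sigma_e^2 = (1 - h2) * sigma_P2`.
#'
#' @param h2 genomic heritability.
#' @param hf2 proportion of genomic variance from C1.
#' @param n_rep phenotypic replicates per line.
#' @param causal_model `"random"` or `"cluster"`.
#' @param dilution number of non-causal markers added to the tested feature.
#' @param sigma_P2 total phenotypic variance.
#' @param replicate_id data-set replicate index.
#' @return an object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(h2 = 0.3, hf2 = 0.3, n_rep = 10,
                                causal_model = "random", dilution = 0,
                                sigma_P2 = 100, replicate_id = 1L) {
  stopifnot(h2 >= 0, h2 <= 1, hf2 >= 0, hf2 <= 1, n_rep >= 1, sigma_P2 > 0)
  structure(list(h2 = h2, hf2 = hf2, n_rep = n_rep,
                 causal_model = causal_model, dilution = dilution,
                 sigma_P2 = sigma_P2, replicate_id = replicate_id,
                 sigma_g1_2 = h2 * hf2 * sigma_P2,
                 sigma_g2_2 = h2 * (1 - hf2) * sigma_P2,
                 sigma_e_2 = (1 - h2) * sigma_P2),
            class = "simulation_scenario")
}

#' Simulate phenotypes from causal marker sets
#'
#' Draws `y = Z g1 + Z g2 + e` with `g1 ~ N(0, G1 sigma_g1^2)` from the C1
#' relationship matrix, `g2 ~ N(0, G2 sigma_g2^2)` from the C2 relationship
#' matrix and iid residuals, replicating each line `n_rep` times. Multivariate
#' normal draws use the eigendecomposition of each relationship matrix with
#' negative eigenvalues clipped at zero. Each generating relationship matrix
#' is scaled to unit mean diagonal so that `sigma_g1^2 + sigma_g2^2 +
#' sigma_e^2` is the realised phenotypic variance: for fully inbred lines the
#' raw `W W'/m` matrix has diagonal near 2, which would otherwise double the
#' genetic contribution relative to the nominal decomposition.
#'
#' @param genotypes a [genotype_data()] object.
#' @param causal a [select_causal_sets()] result.
#' @param scenario a [simulation_scenario()].
#' @param seed optional integer seed.
#' @return data.frame with columns `line_id`, `line` (index), `replicate`,
#'   `y`; the true line-level genetic values are attached as attributes `g1`
#'   and `g2`.
#' @export
simulate_phenotypes <- function(genotypes, causal, scenario, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_lines(genotypes)
  unit_diag <- function(G) G / mean(diag(G))
  g1 <- if (scenario$sigma_g1_2 > 0) {
    mvn_from_G(unit_diag(build_grm(genotypes, causal$C1)$G),
               scenario$sigma_g1_2)
  } else numeric(n)
  g2 <- if (scenario$sigma_g2_2 > 0) {
    mvn_from_G(unit_diag(build_grm(genotypes, causal$C2)$G),
               scenario$sigma_g2_2)
  } else numeric(n)
  li <- rep(seq_len(n), each = scenario$n_rep)
  e <- stats::rnorm(length(li), 0, sqrt(scenario$sigma_e_2))
  y <- (g1 + g2)[li] + e
  out <- data.frame(line_id = genotypes$line_ids[li], line = li,
                    replicate = rep(seq_len(scenario$n_rep), n), y = y,
                    stringsAsFactors = FALSE)
  attr(out, "g1") <- g1
  attr(out, "g2") <- g2
  attr(out, "scenario") <- scenario
  out
}

mvn_from_G <- function(G, sigma2) {
  eg <- eigen(G, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  drop(eg$vectors %*% (sqrt(d * sigma2) * stats::rnorm(length(d))))
}

#' Dilute a causal feature with non-causal markers
#'
#' Returns the feature C1 plus `n_noncausal` markers sampled disjointly from
#' both causal sets, emulating annotation noise in real genomic features.
#'
#' @param causal a [select_causal_sets()] result.
#' @param n_noncausal number of non-causal markers to add.
#' @param genotypes the [genotype_data()] object.
#' @param seed optional integer seed.
#' @return a [feature_set()] of size `length(C1) + n_noncausal`.
#' @export
dilute_feature <- function(causal, n_noncausal, genotypes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_noncausal == 0) {
    return(feature_set(causal$C1, name = "C1+0"))
  }
  pool <- setdiff(seq_len(n_markers(genotypes)), c(causal$C1, causal$C2))
  if (n_noncausal > length(pool)) stop("insufficient non-causal markers")
  extra <- pool[sample.int(length(pool), n_noncausal)]
  feature_set(sort(c(causal$C1, extra)), name = paste0("C1+", n_noncausal))
}

#' The full factorial simulation grid
#'
#' Enumerates the scenario cells of the simulation design. With the default
#' levels — three heritabilities, four feature variance proportions, three
#' replicate numbers, two causal models and twenty dilution levels — the grid
#' has 1,440 cells.
#'
#' @param h2,hf2,n_rep,causal_model,dilution factor levels.
#' @return data.frame with one row per cell.
#' @export
scenario_grid <- function(h2 = c(0.1, 0.3, 0.5),
                          hf2 = c(0.1, 0.2, 0.3, 0.5),
                          n_rep = c(5, 10, 50),
                          causal_model = c("random", "cluster"),
                          dilution = seq(100, 2000, by = 100)) {
  expand.grid(h2 = h2, hf2 = hf2, n_rep = n_rep, causal_model = causal_model,
              dilution = dilution, stringsAsFactors = FALSE,
              KEEP.OUT.ATTRS = FALSE)
}

#' Run set tests over a simulation grid
#'
#' For every distinct combination of (h2, hf2, n_rep, causal_model) in the
#' grid and every data-set replicate, draws causal sets and phenotypes, fits
#' the all-marker GBLUP null model, back-solves marker effects, and evaluates
#' the requested set statistics for the diluted causal feature at every
#' dilution level of that cell plus (optionally) the non-causal null sets.
#' All dilution levels of a cell are evaluated on the same simulated data
#' set, since dilution changes only the tested feature, not the phenotype.
#' All randomness derives from `seed`; the same seed reproduces the table
#' exactly.
#'
#' @param genotypes a [genotype_data()] object (shared across all data sets,
#'   as a fixed panel would be).
#' @param grid a [scenario_grid()]-style data.frame.
#' @param n_datasets independent data sets per cell.
#' @param statistics subset of `c("cvat", "score", "sum_s2", "sum_t2",
#'   "count_05", "count_01")`.
#' @param n_perm permutations per feature.
#' @param null_sets also evaluate the non-causal sets of each data set.
#' @param null_set_sizes passed to [select_causal_sets()].
#' @param mode permutation engine mode.
#' @param seed master seed.
#' @param progress print one line per data set.
#' @return data.frame with one row per (cell, data set, feature, statistic):
#'   scenario columns, `dataset`, `feature`, `feature_type`
#'   (`"causal"`/`"null"`), `dilution`, `size`, `statistic`, `observed`,
#'   `p_empirical`.
#' @export
run_scenario_grid <- function(genotypes, grid, n_datasets = 1,
                              statistics = c("cvat", "score", "sum_s2",
                                             "sum_t2", "count_05", "count_01"),
                              n_perm = 1000, null_sets = TRUE,
                              null_set_sizes = rep(c(100, 250, 500, 1000, 2000), 2),
                              mode = "circular", seed = 1, progress = FALSE) {
  statistics <- match.arg(statistics, several.ok = TRUE,
                          choices = c("cvat", "score", "sum_s2", "sum_t2",
                                      "count_05", "count_01"))
  cells <- unique(grid[, c("h2", "hf2", "n_rep", "causal_model")])
  G_all <- build_grm(genotypes)
  set.seed(seed)
  sub_seeds <- matrix(sample.int(.Machine$integer.max - 1,
                                 nrow(cells) * n_datasets * 3),
                      ncol = 3)
  rows <- list()
  ri <- 0L
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    dilutions <- sort(unique(grid$dilution[grid$h2 == cell$h2 &
                                             grid$hf2 == cell$hf2 &
                                             grid$n_rep == cell$n_rep &
                                             grid$causal_model == cell$causal_model]))
    for (ds in seq_len(n_datasets)) {
      sd3 <- sub_seeds[(ci - 1) * n_datasets + ds, ]
      causal <- select_causal_sets(genotypes, cell$causal_model,
                                   null_set_sizes = null_set_sizes,
                                   seed = sd3[1])
      scen <- simulation_scenario(cell$h2, cell$hf2, cell$n_rep,
                                  cell$causal_model, replicate_id = ds)
      phe <- simulate_phenotypes(genotypes, causal, scen, seed = sd3[2])
      fit <- fit_gblup(phe$y, Z = phe$line, G = G_all)
      eff <- backsolve_effects(fit, genotypes)
      contribs <- contributions_for(eff, genotypes, statistics)

      feats <- lapply(dilutions, function(d) {
        dilute_feature(causal, d, genotypes, seed = sd3[3] %% 2147483L + d)
      })
      f_meta <- data.frame(feature = vapply(feats, `[[`, "", "name"),
                           feature_type = "causal", dilution = dilutions)
      if (null_sets) {
        nf <- lapply(names(causal$null_sets), function(nm) {
          feature_set(causal$null_sets[[nm]], name = nm)
        })
        feats <- c(feats, nf)
        f_meta <- rbind(f_meta,
                        data.frame(feature = names(causal$null_sets),
                                   feature_type = "null", dilution = NA))
      }
      for (fi in seq_along(feats)) {
        fs <- feats[[fi]]
        m_f <- length(fs$marker_idx)
        eng <- null_engine(mode = mode, n_perm = n_perm,
                           seed = sd3[3] + fi)
        for (st in statistics) {
          cv <- contribs[[st]]
          scale <- if (st == "score") 1 / (2 * m_f) else 1
          observed <- sum(cv[fs$marker_idx]) * scale
          pe <- empirical_pvalue(observed, cv, fs$marker_idx, eng,
                                 scale = scale)
          ri <- ri + 1L
          rows[[ri]] <- data.frame(
            h2 = cell$h2, hf2 = cell$hf2, n_rep = cell$n_rep,
            causal_model = cell$causal_model, dataset = ds,
            feature = f_meta$feature[fi],
            feature_type = f_meta$feature_type[fi],
            dilution = f_meta$dilution[fi], size = m_f, statistic = st,
            observed = observed, p_empirical = pe$p_empirical,
            stringsAsFactors = FALSE)
        }
      }
      if (progress) {
        message(sprintf("cell %d/%d dataset %d done", ci, nrow(cells), ds))
      }
    }
  }
  do.call(rbind, rows)
}

contributions_for <- function(eff, genotypes, statistics) {
  out <- list()
  for (st in statistics) {
    out[[st]] <- switch(st,
      cvat = per_marker_contributions(eff, genotypes, "cvat"),
      score = per_marker_contributions(eff, genotypes, "score"),
      sum_s2 = per_marker_contributions(eff, genotypes, "sum", basis = "s2"),
      sum_t2 = per_marker_contributions(eff, genotypes, "sum", basis = "t2"),
      count_05 = per_marker_contributions(
        eff, genotypes, "count", t0 = stats::qt(0.975, eff$df_e[1])),
      count_01 = per_marker_contributions(
        eff, genotypes, "count", t0 = stats::qt(0.995, eff$df_e[1])))
  }
  out
}
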