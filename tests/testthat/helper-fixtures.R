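# Shared fixtures, generated once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# small inbred panel with block LD
tiny_panel <- function() {
  fixture("tiny_panel", function() {
    simulate_genotypes(n_lines = 60, m = 1500, n_chrom = 3, seed = 101)
  })
}

# a fitted GBLUP model with real signal on the tiny panel
tiny_fit <- function() {
  fixture("tiny_fit", function() {
    geno <- tiny_panel()
    causal <- select_causal_sets(geno, "random", n_c1 = 30, n_c2 = 120,
                                 null_set_sizes = c(60, 60), seed = 102)
    phe <- simulate_phenotypes(geno, causal,
                               simulation_scenario(h2 = 0.5, hf2 = 0.5,
                                                   n_rep = 4), seed = 103)
    fit <- fit_gblup(phe$y, Z = phe$line, G = build_grm(geno))
    list(geno = geno, causal = causal, phe = phe, fit = fit,
         eff = backsolve_effects(fit, geno))
  })
}

# deterministic dense genotype matrix (no LD structure assumptions)
random_genotypes <- function(n, m, seed = 1, maf_min = 0) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.5)
  A <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  poly <- apply(A, 2, function(a) length(unique(a)) > 1)
  genotype_data(A[, poly, drop = FALSE], maf_min = maf_min)
}

# VCF fixture with a known QC outcome: of 11 records, records 2 and 3 fail
# QUAL (<= 500), record 5 fails call rate (0.7), record 8 fails MAF (0.025),
# record 11 is not a biallelic SNP; 6 markers survive (1, 4, 6, 7, 9, 10).
# Record 1 carries three missing calls (call rate 0.85, passing) to exercise
# mean imputation.
write_fixture_vcf <- function(path) {
  n <- 20
  gt_line <- function(counts) {
    vapply(counts, function(x) {
      if (is.na(x)) "./." else c("0/0", "0/1", "1/1")[x + 1]
    }, character(1))
  }
  recs <- list(
    list(pos = 100, qual = 900, counts = c(rep(NA, 3), rbinom(n - 3, 2, 0.3))),
    list(pos = 200, qual = 400, counts = rbinom(n, 2, 0.3)),
    list(pos = 300, qual = 500, counts = rbinom(n, 2, 0.3)),   # QUAL must be > 500
    list(pos = 400, qual = 800, counts = rbinom(n, 2, 0.4)),
    list(pos = 500, qual = 900,
         counts = c(rep(NA, 6), rbinom(n - 6, 2, 0.3))),       # call rate 0.7
    list(pos = 600, qual = 900, counts = rbinom(n, 2, 0.25)),
    list(pos = 700, qual = 700, counts = rbinom(n, 2, 0.45)),
    list(pos = 800, qual = 900, counts = c(1, rep(0, n - 1))), # MAF 0.025
    list(pos = 900, qual = 900, counts = rbinom(n, 2, 0.35)),
    list(pos = 950, qual = 900, counts = rbinom(n, 2, 0.3)),
    list(pos = 980, qual = 900, counts = rbinom(n, 2, 0.3), alt = "AT"))
  # make sure the "passing" records are truly polymorphic with MAF >= 0.05
  for (i in c(2, 3, 4, 6, 7, 9, 10)) {
    while (TRUE) {
      f <- mean(recs[[i]]$counts) / 2
      if (min(f, 1 - f) >= 0.1) break
      recs[[i]]$counts <- rbinom(n, 2, 0.3)
    }
  }
  while (TRUE) {
    f <- mean(recs[[1]]$counts, na.rm = TRUE) / 2
    if (min(f, 1 - f) >= 0.1) break
    recs[[1]]$counts <- c(rep(NA, 3), rbinom(n - 3, 2, 0.3))
  }
  samples <- sprintf("L%02d", seq_len(n))
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    lines <- c(lines, paste(c("chr1", r$pos, sprintf("snp%02d", i), "A",
                              if (is.null(r$alt)) "G" else r$alt,
                              r$qual, "PASS", ".", "GT", gt_line(r$counts)),
                            collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(recs)
}
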