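# gblupset

Marker-set (genomic feature) association testing derived from genomic BLUP,
for quantitative traits measured on genotyped panels — in particular panels
of inbred lines with replicated phenotypes.

Most complex traits are shaped by many loci of small effect, so single-marker
scans on a few hundred lines are underpowered. `gblupset` instead tests
whether a *set* of markers — the SNPs in a gene, a GO term, a pathway, any
annotated feature — is associated with the trait more strongly than a random
marker set of the same size (a competitive null). All statistics come from a
single linear mixed-model fit, which keeps large feature catalogs cheap.

## The model and statistics

The base model is GBLUP,

    y = Xb + Zg + e,   g ~ N(0, G sigma_g^2),   e ~ N(0, I sigma_e^2),

with `G = WW'/m` the genomic relationship matrix from centered/scaled allele
counts. Variance components are estimated by average-information REML (with
an exact line-mean collapse for replicated records). From the predicted
genomic values, per-marker effects are back-solved as `s = W'(WW')^- g_hat`
with variances and t-statistics on `df_e = n - tr(H)` degrees of freedom.
Four set statistics are computed for a feature `f` of `m_f` markers:

* **CVAT** (covariance association test): `T = g_hat' g_hat_f`, the
  covariance between the total and the feature genomic values;
* **Score** (SKAT-type): `T = 1/2 e_hat' Z G_f Z' e_hat`, a quadratic form
  in the projected residuals with the feature kernel;
* **Sum**: `sum(s_i^2)` or `sum(t_i^2)` over the feature;
* **Count**: markers with `|t| > t0`, with a hypergeometric parametric null.

Significance comes from a competitive null: per-marker contributions are
rotated around a circularized genome (preserving local LD structure) or
random marker sets are drawn, and the one-tailed empirical p-value is
`(#{T_perm >= T_obs} + 1) / (n_perm + 1)`. Extensions include gene-level
decomposition of CVAT, multi-component (GFBLUP) models, and two-trait fits
with the four within-/across-trait covariance statistics.

A synthetic-data module generates an inbred-line panel with haplotype-block
LD and simulates phenotypes from feature-causal and background-causal marker
sets over a full factorial scenario grid (heritability, feature share,
replicates, causal geometry, dilution); evaluation utilities compute F1
detection power and cross-validated predictive ability of feature models.

## Worked example

```r
library(gblupset)

geno   <- simulate_genotypes(n_lines = 150, m = 6000, n_chrom = 3, seed = 21)
causal <- select_causal_sets(geno, "random", null_set_sizes = c(100, 500), seed = 22)
phe    <- simulate_phenotypes(geno, causal,
                              simulation_scenario(h2 = 0.5, hf2 = 0.5, n_rep = 10),
                              seed = 23)

fit <- fit_gblup(phe$y, Z = phe$line, G = build_grm(geno))
fit
#> GBLUP fit: 1500 observations on 150 lines, 1 genomic component(s)
#>   sigma_g2: 22.07   sigma_e2: 53.16
#>   h2: 0.454   logLik: -3717.789   df_e: 1369.3

eff <- backsolve_effects(fit, geno)
cvat(eff, geno, dilute_feature(causal, 0, geno),
     null_engine(n_perm = 5000, seed = 25))
#> CVAT: T = 183.539 (feature 'C1+0', m_f = 100)
#>   empirical p = 0.0003999 (5000 permutations)

cvat(eff, geno, feature_set(causal$null_sets[[1]], "null_100"),
     null_engine(n_perm = 5000, seed = 26))
#> CVAT: T = 112.919 (feature 'null_100', m_f = 100)
#>   empirical p = 0.2372 (5000 permutations)
```

The trait was simulated at heritability 0.5 with half the genetic variance
in the 100-marker causal set; the fit recovers `h2 ≈ 0.45`. The causal
feature's covariance statistic is far outside its circular-permutation null
(p ≈ 4e-4, the add-one floor region at 5,000 rotations), while a size-matched
non-causal set is unremarkable (p ≈ 0.24).

Real data come in through `read_genotypes()` (VCF with QUAL/call-rate/MAF
QC, or TSV matrix + marker map), `read_phenotypes()`,
`map_markers_to_features()` (GFF3/BED gene intervals + GMT gene sets), and a
thin command-line front end in `inst/cli/gblupset.R` with subcommands
`simulate`, `fit`, `settest`, `grid`.

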