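---
title: "Marker-set association testing from GBLUP: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-set association testing from GBLUP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Complex-trait variation is typically spread over many loci of small effect.
Single-marker association scans on panels of modest size therefore miss most
of the signal. Set tests aggregate evidence over a *genomic feature* — the
markers in a gene, a GO term, a pathway, any externally defined marker set —
and ask whether the feature as a whole is associated with the trait more
strongly than a random marker set of the same size (a *competitive* null).
`gblupset` implements a family of such tests that are all derived from a
single genomic BLUP fit, together with the simulation machinery needed to
study their operating characteristics on a synthetic inbred-line panel.

# The linear mixed model

The base model is GBLUP:

$$ y = Xb + Zg + e, \qquad
   g \sim N(0, G\sigma_g^2), \quad e \sim N(0, I\sigma_e^2), $$

where $y$ holds (possibly replicated) phenotypic records, $Z$ maps records to
lines, and $G = WW'/m$ is the genomic relationship matrix built from the
centered and scaled allele counts, $w_i = (a_i - 2p_i)/\sqrt{2p_i(1-p_i)}$
with $p_i$ the minor allele frequency. Because the columns of $W$ are
centered, $G$ is singular; every inverse of $G$ or $WW'$ in the package is an
eigenvalue-thresholded pseudo-inverse (relative cutoff $10^{-8}\lambda_{max}$).

Variance components are estimated by average-information REML. The
implementation details that matter:

* **Collapsed fitting.** When the fixed-effect design is constant within
  line and there is no extra random effect, the model is fitted on line
  means with the within-line residual sum of squares absorbed analytically
  into $\sigma_e^2$. This is exact (the within-line contrasts are error
  contrasts independent of the line means) and makes the per-iteration cost
  independent of the number of replicates — essential for scenarios with 50
  records per line. The restricted likelihood then differs from the
  observation-level value by a data-constant; likelihood comparisons are
  only made within one representation.
* **Constrained steps.** Variances are floored at $10^{-8}$ times the
  phenotypic variance. AI updates are capped (ill-conditioned AI matrices
  can propose astronomically large steps), step-halved until the restricted
  likelihood does not decrease, and re-solved for the free parameters when a
  variance is pinned at its floor with an outward-pointing score (an active
  set strategy); a projected-gradient direction is the fallback. The
  accepted trajectory is therefore monotone, which the tests assert.
* **Convergence** at $|\Delta\ell| < 10^{-6}$ and relative parameter change
  $< 10^{-5}$, at most 200 iterations; non-convergence is a warning flag on
  the fit, never a silent success.
* **Two traits.** The bivariate model stacks both traits with genetic
  covariance $G \otimes S_g$ and trait-specific residual variances; the
  residual covariance between traits is fixed at zero (traits recorded on
  different individuals or environments), and per-trait replicate-within-line
  effects can be added. $S_g$ is parameterized linearly; an update that
  leaves the PSD cone is bent onto its boundary with a warning. We chose the
  linear parameterization over a Cholesky one because it keeps the generic
  AI engine (scores and average information are linear in the structures)
  and the bending step is transparent; the duplicate-trait edge case
  (correlation 1) sits exactly on the boundary either way.

## Heritability on an inbred panel

For fully inbred lines the allele counts are 0/2 and the $2p(1-p)$ scaling
gives $\mathrm{diag}(G) \approx 2$. The genomic heritability reported by the
package is the genetic fraction of the per-line phenotypic variance,
$h^2 = \sigma_g^2\,\overline{\mathrm{diag}(G)} \,/\,
(\sigma_g^2\,\overline{\mathrm{diag}(G)} + \sigma_e^2)$, so that it matches
the heritability a simulation generates. For the same reason the phenotype
generator scales each generating relationship matrix to unit mean diagonal:
the nominal variance decomposition (total 100) is then the realized
phenotypic variance, which the tests verify.

# From genomic values to marker effects

The fit yields $\hat g = G\hat\sigma_g^2 \hat V^{-1}(y - X\hat b)$. Marker
effects are back-solved as $\hat s = W'(WW')^{-}\hat g$, with
$\mathrm{Var}(\hat s) = W'(WW')^{-}\mathrm{Var}(\hat g)(WW')^{-}W$ evaluated
on its diagonal (the full $m \times m$ matrix is only returned on request and
refused above $m = 5000$). $\mathrm{Var}(\hat g)$ is the variance of the
predictor, computed directly as $\hat\sigma_g^4\, G P G$ with $P$ the
projection form of $\hat V^{-1}$; the prediction-error covariance
$C^{gg} = G\hat\sigma_g^2 - \mathrm{Var}(\hat g)$ is also stored. Single
marker t-statistics $t_j = \hat s_j / \sqrt{\mathrm{Var}(\hat s_j)}$ are
referred to a t distribution with $df_e = n - \mathrm{tr}(H)$ degrees of
freedom, where $H$ is the hat matrix of the penalized fit; two-sided
p-values are used (the count statistic thresholds $|t|$, which is sign-free).
A variance floor of $10^{-12}$ prevents infinite t-statistics; floored
markers are flagged with $t = 0$, $p = 1$.

# The four set statistics and their common engine

Every statistic is a sum of per-marker contributions, which is what lets one
permutation engine serve all of them:

| statistic | contribution of marker $i$ | feature statistic |
|---|---|---|
| CVAT | $\hat s_i\,(\hat g' w_i)$ | $T = \hat g'\hat g_f$ |
| Score (SKAT-type) | $(\hat e' Z w_i)^2$ | $T = \tfrac{1}{2m_f}\sum_{i\in f} c_i$ |
| Sum | $\hat s_i^2$ or $t_i^2$ | $T = \sum_{i\in f} c_i$ |
| Count | $I(|t_i| > t_0)$ | $T = \sum_{i\in f} c_i$ |

The CVAT statistic decomposes as
$\hat g'\hat g_f = \hat g_f'\hat g_f + \hat g_r'\hat g_f$ (feature variance
plus covariance with the rest of the genome); both evaluation routes are
computed and must agree. The score statistic is identically
$\tfrac12 (y-X\hat b)'\hat V^{-1} Z G_f Z' \hat V^{-1}(y-X\hat b)$; the test
suite verifies the two forms against each other on dense instances. Its
default null model is the all-marker GBLUP fit (fitted once for any number
of features); refitting with the feature's markers excluded from the
relationship matrix is available per feature at the cost of one REML fit.
The count threshold is specified as a single-marker p-value cutoff
(defaults 0.05 and 0.01) converted through the $t(df_e)$ quantile, and its
parametric null is the hypergeometric upper tail
$P(X \ge T)$ for $X \sim \mathrm{Hyper}(m, m_a, m_f)$.

**A degeneracy worth knowing about.** With the all-marker null model,
$\hat s = (\hat\sigma_g^2/m)\, W'Z'\hat e$ exactly (the column space of $W$
equals the range of $G$), so the Sum($\hat s^2$) contributions are
proportional to the Score contributions and the two tests give identical
permutation p-values. They differ once the sum uses $t_i^2$ (the effect
variances are not constant across markers), once the score null excludes
the feature, or once the score p-value comes from the gamma approximation.
This identity is a property of the method family, not a bug; the package
keeps both statistics because their other variants do differ.

The CVAT extensions follow the same pattern: gene-level decomposition
reports $\hat g'\hat g_{f_i}$ per gene and per SNP (gene sizes vary), with
overlapping genes evaluated independently and flagged; the multi-trait
statistics $T_M = \hat g_1'\hat g_{f_1}$, $T_F = \hat g_2'\hat g_{f_2}$,
$T_{MF} = \hat g_1'\hat g_{f_2}$, $T_{FM} = \hat g_2'\hat g_{f_1}$ test
within- and across-trait covariance with a feature.

# The competitive null

Two null engines are provided.

*Circular permutation* treats the genome as a circle in marker order
(chromosome order is configurable), rotates the whole contribution vector by
a random offset, and re-sums at the feature's original positions. This
preserves the local correlation structure of the contributions — the key
requirement for a fair competitive null under linkage disequilibrium — and
preserves their multiset exactly. For a feature of size $m_f$ the rotation
sums for *all* $m$ offsets are a circular cross-correlation, computed by FFT
in $O(m\log m)$ when $n_{perm} \cdot m_f$ is large (the tests check FFT and
direct indexing agree to $10^{-9}$); draws are then indexed by the sampled
offsets.

*Random-set sampling* draws $m_f$ markers without replacement from the null
domain. The domain can be restricted (e.g. genic markers only), which
restricts both rotation and sampling.

The empirical p-value is the add-one estimator
$p = (\#\{T_{perm} \ge T_{obs}\} + 1)/(n_{perm}+1)$: the plain proportion
can return an exact zero, which misrepresents a Monte Carlo tail; the raw
proportion remains available by flag. Ties count against the feature
(conservative), with strict `>` available. The p-values are uniform under an
exchangeable null — the calibration test simulates a trait with genuine
polygenic signal and 500 random marker sets, whose p-values must pass a
Kolmogorov–Smirnov uniformity check. Note that uniformity requires the
feature to be exchangeable with its rotations: a feature deliberately chosen
to avoid all causal markers is *conservative* under this null, which is the
intended behaviour of a competitive test, not a calibration failure.
Satterthwaite gamma p-values for the score test match moments against the
permutation sample, keeping the approximation aligned with the competitive
null (the analytic trace alternative is not implemented).

# The synthetic panel and simulation design

The generator emulates a reference panel of fully inbred lines:

* **Genotypes.** Haplotype blocks of 50 markers; within a block, 8 founder
  haplotypes are drawn from a latent AR(1) Gaussian copula (autocorrelation
  0.95) with marginal allele frequencies uniform on [0.05, 0.5]; each line
  copies one founder per block with a 2% per-marker flip rate. Inbred mode
  doubles a single haplotype (allele counts 0/2 only); an outbred mode sums
  two. Markers failing a realized-MAF filter at 0.05 are dropped, as a real
  panel's QC would. This yields strong within-block and negligible
  between-block LD — the structure that makes circular permutation a
  meaningful competitive null — but it does not emulate long-range LD,
  population structure, allele-frequency spectra, or selection. Conclusions
  from passing tests are therefore structural (calibration, relative power,
  concordance between statistics), not quantitative predictions for any real
  panel.
* **Causal sets.** 1,000 causal markers split into C1 (100, the feature
  causal set) and C2 (900, background), drawn genome-wide (*random* model)
  or as 5 markers from each of 20 non-overlapping 50-marker regions
  (*cluster* model; the per-region count follows from 100/20, and regions
  are spans of consecutive markers). Non-causal *null sets* measure false
  positives; at 20k markers the original null-set sizes (up to 10k) are not
  representable, so the default is 10 sets sized 100–2,000, matching the
  dilution-feature size range.
* **Phenotypes.** $y = Zg_1 + Zg_2 + e$ with
  $\sigma_{g1}^2 = h^2 h_f^2 \sigma_P^2$,
  $\sigma_{g2}^2 = h^2(1-h_f^2)\sigma_P^2$,
  $\sigma_e^2 = (1-h^2)\sigma_P^2$, $\sigma_P^2 = 100$; multivariate draws
  use eigendecompositions with negative eigenvalues clipped at zero.
* **The grid.** Heritabilities $\{0.1, 0.3, 0.5\}$, feature shares
  $\{0.1, 0.2, 0.3, 0.5\}$, replicates $\{5, 10, 50\}$, two causal models,
  and twenty dilution levels $100, 200, \dots, 2000$ — 1,440 cells. The
  dilution factor's grid levels start at 100 because the cell count requires
  twenty levels; analyses over "the dilution range" prepend the undiluted
  feature, giving 21 features per series. Since dilution changes only the
  tested feature, all dilution levels of a cell are evaluated on one
  simulated data set.

# Evaluation

Detection power is summarized by the F1 score at a set-test p cutoff of
0.05: causal features are positives, null sets negatives. Power can be
reported per dilution level or with each data set's p-values first averaged
over the dilution range. Predictive ability of the two-component (feature +
rest) model is the mean Spearman correlation, over repeated random 90/10
line-level splits, between the validation lines' total genomic values
predicted from the training phenotypes and the values predicted with all
phenotypes observed — prediction against the full-data predictions, as the
cross-validation design specifies; correlating against observed line means
is available as a flagged alternative. Splits are independent draws, not a
partition, and are made at the line level to respect the replicate
structure.

# Problem sizes used in the shipped analyses

The packaged tests and the acceptance script run the study at desk scale,
chosen once: a 200-line x 20,000-marker panel; 16 data sets and 2,000
rotations for the statistic-concordance analysis; 20 data sets and 1,000
rotations for the cluster-model power curve; 500 features and 2,000
rotations for null calibration; 20 replicate fits per heritability level
for REML recovery; 14 data sets x 21 dilution features x 20 cross-validation
splits for the significance-vs-predictive-ability correlation. At this scale
the concordance correlations and the power floor reproduce the original
study's structure well; the significance-vs-predictive-ability rank
correlation is attenuated (roughly 0.35–0.47 across seeds) relative to the
original (~0.6), because the predictive-ability estimate from 20 splits on
200 lines is noisy — rank-correlation attenuation, not a method difference.
Raising the split count and panel size moves it toward the original value.

# Known limitations

* The score test's exclude-feature null refits one model per feature;
  for catalogs of thousands of features use the all-marker default.
* The two-trait fitter is dense ($O((N_1+N_2)^3)$ per iteration) and meant
  for line-level or lightly replicated data; the collapsed path covers only
  single-trait models.
* No weighted relationship matrices, no more than two traits, no pedigree
  matrices, and no self-contained (variance-component LRT) null — the test
  family is strictly competitive.
* Whether the original study's figure-level comparisons used circular
  rotation or random column sampling for every statistic is not stated;
  defaults here follow the circular procedure, and both engines are exposed.
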