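---
title: "Methods: longitudinal gut-microbiota cohorts and microbiability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal gut-microbiota cohorts and microbiability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This package implements the statistical core of a longitudinal
gut-microbiota cohort analysis: from a samples × taxa count table and
host metadata through core-microbiota detection, α/β-diversity dynamics,
permutation-based community inference, community typing, and finally
Bayesian estimation of *microbiability* — the fraction of host
phenotypic variance attributable to the gut microbial community. The
motivating setting is a cohort of sport horses sampled at two time
points roughly eight months apart, but nothing in the code is specific
to horses: any host cohort with repeated 16S-style count data fits.

```{r setup, message = FALSE}
library(equimicrobiome)
```

## The synthetic cohort: what it emulates and what it does not

Because cohort phenotype data of this kind are rarely deposited, the
package ships a generator, `simulate_cohort()`, whose defaults encode
the study conditions the analyses are designed for:

* **185 hosts × 2 time points**, sampled at 10,000–60,000 reads per
  sample (drawn uniformly).
* **A stable prevalent core**: 29 designated core genera whose base
  relative weights are drawn log-uniformly in a high band, so that they
  carry roughly three quarters of the reads and pass a 0.1% detection /
  99% prevalence rule at both time points.
* **A volatile rare fraction**: the remaining taxa get low, heavy-tailed
  base weights, host-specific presence/absence patterns, and flip
  presence between time points with probability `rare_turnover`
  (default 0.3). Host-specific log-normal signatures apply with full
  `host_sd` (default 1) to rare taxa and a quarter of it to core taxa —
  prevalent commensals are empirically far more stable than rare taxa,
  and this split reproduces the qualitative signature of real cohorts:
  between-host divergence exceeds within-host divergence, and rare taxa
  drive the temporal turnover.
* **Overdispersion**: expected compositions are perturbed by a
  Dirichlet draw with concentration `overdispersion` (default 500)
  before multinomial sampling at the drawn depth. 500 keeps a 1–5%
  core taxon essentially always above the 0.1% detection threshold
  while still producing realistic extra-multinomial noise; `Inf`
  disables the Dirichlet layer entirely.
* **Phenotypes under the microbiability model**:
  `y = μ + Xβ + u_m + u_g + ε` with `u_m ~ N(0, σ²_m M)` where `M` is
  the microbial kernel computed from the *generated* table (CSS-log
  path), `u_g ~ N(0, σ²_H K)` with a block-by-breed kinship
  (within-breed relatedness 0.25 — breed is the only genetic-structure
  signal available without a pedigree), and component variances scaled
  so that σ²_m/(σ²_m+σ²_H+σ²_e) equals the configured `true_m2`
  exactly. Each continuous phenotype gets a bounded companion
  `freq_*` column through a logistic map of the standardized latent
  value, mimicking scan-sampled behaviour frequencies; the modelling
  path consumes the continuous scale, and the logistic link is a
  modelling convenience, not an empirical claim about behaviour
  distributions.

One global integer seed expands into independent sub-seeds for the
counts, tree and phenotype stages, so each stage can be regenerated
independently and the whole cohort is bit-reproducible.

What the generator does **not** emulate: read-level artefacts (chimeras,
primer bias), compositional correlations between taxa beyond the
Dirichlet layer, seasonal covariates, diet, or measurement error in the
phenotypes. Passing parameter-recovery tests on this generator therefore
shows that the estimator is correct *under its own model assumptions*;
it does not certify performance on real cohorts where the kernel is a
misspecified summary of the true host–microbiome relationship.

## Table transforms

`rarefy()` subsamples each library without replacement to a common
depth (the classical choice is the smallest library, e.g. 10,000
reads), dropping and reporting shallower samples. `aggregate_taxa()`
sums counts over lineages at a chosen rank and pools taxa unclassified
at that rank into one `unclassified_<parent>` bucket per parent, so
reads are conserved. `css_log()` implements cumulative-sum scaling with
a log2 transform: per sample the scaling factor is the sum of counts at
or below the chosen quantile (default 0.5) of that sample's nonzero
counts, and values are `log2(count/s_j · S + 1)` with `S` the median
scaling factor. The fixed median quantile rather than an adaptive
quantile search keeps the transform reproducible and documented; the
quantile is exposed as an argument for sensitivity analysis. The +1
pseudo-count keeps zeros at exactly zero.

`core_microbiota()` defaults to detection 0.1% and prevalence 99%,
evaluated within each time point and intersected. The 99% default (with
99.9% available via the `prevalence` argument) reflects the reading of
the rule under which a 29-genus core is actually reported for a cohort
of this size; at 185 hosts a 99.9% prevalence over ~370 samples is
equivalent to "no more than zero failures rounded down", which is
stricter than the described core.

## Diversity

`alpha_diversity()` reports observed richness, bias-corrected Chao1
`S + F1(F1−1)/(2(F2+1))` (defined even without doubletons), Shannon
entropy in natural log (the base is a convention; natural log is the
ecology default), and Fisher's α solved from `S = α ln(1 + N/α)` by
bracketed root finding to 1e-10. "Fisher diversity" is taken to mean
Fisher's α of the log-series model. Indices are defined on counts, so
the function refuses non-integer tables.

`bray_curtis()` and `unifrac()` (unweighted, and the normalized
weighted variant bounded in [0, 1]; the raw weighted form is available
via `normalized = FALSE`) produce `dist` objects consumed by every
downstream routine. On a star phylogeny with equal branch lengths the
normalized weighted UniFrac collapses to Bray–Curtis on relative
abundances, which the test suite asserts to 1e-9 as a limit-case check.
A pair of all-zero samples has no defined dissimilarity; it is reported
as 0 with a warning rather than NaN.

`dispersion()` embeds the distance matrix by principal coordinates
(spatial centroids; Bray–Curtis is non-Euclidean, so negative
eigenvalues are handled by the standard correction) and permutes a
one-way F on the distances-to-centroid — the device used to ask whether
the cohort is more heterogeneous at the second time point.

## Permutation inference

`permanova()` uses sequential (type-I) sums of squares in the order the
terms are written, matching the convention of sequential-SS F tests on
distance matrices; term order therefore matters and is the user's
choice. With repeated measures, `strata = host` restricts permutations
to within-host label swaps, the appropriate null for a time effect in a
paired design. All permutation p-values use the add-one estimator
`(1 + #{perm ≥ obs})/(1 + n_perm)` and so lie in (0, 1].

`anosim_test()` reports the rank-based R statistic; `simper_contrib()`
decomposes average between-group Bray–Curtis dissimilarity into
per-taxon contributions normalized to sum to one; `nmds()` minimizes
Kruskal stress-1 over monotone-regressed dissimilarities with multiple
random starts (non-convergence is flagged, not thrown);
`fit_covariates()` measures per-covariate r² on the ordination scores
(continuous: best-fitting direction; categorical: centroid fit), with
Benjamini–Hochberg adjustment across the covariates of one call and a
"combined effect size" equal to the sum of r² over covariates passing
adjusted p < 0.05. Because covariates are generally correlated, that
sum is *not* an orthogonal variance partition and is labelled
accordingly. `delta_phenotypes()` builds within-host T2 − T1
differences so that time-varying associations are not confounded by
host level differences, and `cross_correlate()` computes the full
taxa × phenotype Pearson grid with one BH family per call and
significance tiers at adjusted p < 0.05 and < 0.10.

## Community typing

`pam_clusters()` wraps k-medoids (BUILD + SWAP) on any distance
matrix. SWAP exchanges one medoid at a time and can stall in a local
optimum even on six points, so the deterministic BUILD start is
complemented by seeded random restarts (default 10) and the best local
optimum kept; on instances small enough to enumerate, this reliably
reaches the exhaustive optimum, which the tests assert. Singleton
clusters get silhouette 0 by the usual convention. `select_k()` scans
k = 2..10 (the conventional community-typing range) and flags
"reasonable structure" only when the best silhouette coefficient
exceeds 0.5 — for a cohort without enterotype-like structure the
expected outcome is `reasonable = FALSE`, and the acceptance suite
reproduces that negative finding on structure-free cohorts.

## Microbiability

The headline estimator. `microbial_kernel()` builds
`M = W W′ / k` from the column-centered CSS-log matrix, rescaled to
unit mean diagonal so that σ²_m sits on the phenotype-variance scale;
a minimal diagonal jitter is recorded if rounding leaves a marginally
negative eigenvalue. `microbiability()` then fits

y = Xβ + u_m + u_g + e,  u_m ~ N(0, σ²_m M),  u_g ~ N(0, σ²_H K),
e ~ N(0, σ²_e I)

by Gibbs sampling: flat priors on the fixed effects (intercept, breed,
discipline, time), scaled-inverse-χ² priors (ν = 5, scale from half the
phenotype variance split equally across components) on each variance.
Random effects are sampled in the eigenbasis of their kernel: writing
`u = U√D α` with `α ~ N(0, σ² I)`, the full conditional of α factorizes
into independent scalar normals because `(U√D)′(U√D) = D` is diagonal,
so a 30,000-iteration chain (default; burn-in 2,000, thinning 10) costs
seconds, not hours, at n = 400. Each sample appears as its own record
with time as a fixed effect — the printed mixed model's structure —
rather than as within-host deltas.

Two m² definitions are provided because the field's verbal definition
and a commonly printed formula disagree: the default `"total"`
definition σ²_m/(σ²_m+σ²_H+σ²_e) is the share of *total* phenotypic
variance and is bounded in [0, 1], consistent with describing m² as "a
percentage of the phenotypic variance"; the `"literal"` form
σ²_m/(σ²_H+σ²_e) omits the focal component from the denominator
(presumably a typographical heritability-style slip) and can exceed 1.
Both are computed per draw; the literal ratio is never smaller.

Chain health is reported as an autocorrelation-based effective sample
size and a split-chain potential-scale-reduction factor on the m²
draws. With an identity-like kernel the microbial and residual
components are unidentifiable and the split mixes arbitrarily slowly;
this surfaces as a low ESS warning rather than failing silently.

### Parameter recovery and calibration scales

The acceptance suite runs the estimator at n = 400 samples × 100 taxa
(true m² ∈ {0.10, 0.25, 0.40}, ten replicate cohorts each), requiring
absolute bias below 0.05 and ≥ 8/10 credible-interval coverage, and at
n = 300 with true m² = 0 requiring posterior means below 0.10 in
≥ 9/10 replicates. Permutation-test calibration uses 500 structure-free
replicates at n = 20 with 999 permutations, a size at which the
Monte-Carlo standard error of a 5% rejection rate is about one point.
The enterotype screen uses 100 structure-free cohorts of 20 hosts.
These problem sizes are the package's chosen trade-off between
Monte-Carlo resolution and a test suite that completes in minutes on a
single core; the same functions run unchanged at full cohort scale.

## Known limitations

* The kernel treats taxa as exchangeable features; phylogenetic
  weighting of the kernel is not implemented.
* PERMANOVA effect sizes are sequential; marginal (type-III style)
  partitioning is not offered.
* `fit_covariates()` operates on ordination scores, as the classical
  implementation does, not on the full distance matrix; with heavily
  compressed ordinations the r² can differ from distance-based effect
  sizes.
* The generator's Dirichlet-multinomial layer does not model taxon–taxon
  interaction networks, and its kinship is a breed-block stand-in, not
  a pedigree.
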