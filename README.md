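# equimicrobiome

Statistical pipeline for longitudinal gut-microbiota cohort studies —
written for the kind of design where a cohort of hosts (the motivating
case: ~185 sport horses) is sampled at two time points, yielding a
samples × taxa 16S count table, rich host metadata (breed, discipline,
housing, behaviour frequencies, hematology) and the questions:

* Which taxa form a stable **core microbiota**, and how do α- and
  β-diversity shift over time?
* Is community variation structured by host identity, time, or
  husbandry covariates (**PERMANOVA / ANOSIM / SIMPER / NMDS +
  covariate fitting**, all permutation-based)?
* Do samples fall into discrete community types (**PAM enterotyping**
  with silhouette-based selection and the SC > 0.5 "reasonable
  structure" rule)?
* How much host phenotypic variance does the microbial community carry —
  the **microbiability** m²?

The headline estimator is a Bayesian mixed model fitted by Gibbs
sampling,

```
y = Xβ + u_m + u_g + e,   u_m ~ N(0, σ²_m M),   u_g ~ N(0, σ²_H K),
m² = σ²_m / (σ²_m + σ²_H + σ²_e)
```

where `M` is the microbial relationship matrix `W W′/k` built from the
column-centered CSS-log abundance matrix (the microbial analogue of a
genomic relationship matrix) and `K` an optional host kinship. Fixed
effects get flat priors; variances get weakly-informative
scaled-inverse-χ² priors; random effects are sampled in the eigenbasis
of their kernel, which makes 30,000-iteration chains cheap at cohort
scale. A literal heritability-style ratio σ²_m/(σ²_H+σ²_e) is available
as `definition = "literal"`.

Because real cohort phenotypes of this kind are rarely deposited, the
package includes a first-class synthetic-cohort generator
(`simulate_cohort()`) with known ground truth — core/rare structure,
host signatures, temporal turnover, Dirichlet-multinomial counts, and
phenotypes generated under the model above with configurable true m² —
used throughout the tests for parameter recovery.

## Worked example

```r
library(equimicrobiome)

cfg <- cohort_config(n_hosts = 60, n_taxa = 120, n_core_taxa = 29,
                     depth_range = c(10000, 30000),
                     true_m2 = 0.25, true_h2 = 0.1, seed = 2024)
cohort <- simulate_cohort(cfg)
#> synthetic_cohort: 60 hosts x 2 time points, 120 taxa ( 29 core ), true m2 = 0.25

# stable core at genus level, consistent across both time points
genus <- aggregate_taxa(cohort$table, "genus")
core <- core_microbiota(genus, timepoints = cohort$metadata$timepoint)
length(core)
#> [1] 29

# host identity structures the community
d <- bray_curtis(cohort$table)
anosim_test(d, cohort$metadata$host_id, n_perm = 999, seed = 1)
#>     term statistic p_value
#> 1 groups  0.423338   0.001

# microbiability of a phenotype simulated with true m2 = 0.25
fit <- microbiability(pheno_1 ~ breed + discipline + timepoint,
                      cohort$metadata,
                      microbial_kernel(css_log(cohort$table)),
                      kinship = expand_kinship(cohort$kinship,
                                               cohort$metadata$host_id,
                                               rownames(cohort$metadata)),
                      seed = 1)
fit
#> Bayesian microbiability model: pheno_1 ~ breed + discipline + timepoint
#> n = 120  chain: 2800 retained draws ( 30000 iterations, burn-in 2000 , thin 10 )
#> m2 = 33.0% +/- 9.7% (95% CI 15.3% - 53.1%)

# no enterotype-like structure in this cohort
select_k(d, 2:10, seed = 1)
#> PAM community typing: k = 2  sizes: 43/77
#> silhouette coefficient SC = 0.205 (no reasonable structure, SC <= 0.5)
```

At this small size (120 samples) a single posterior mean sits well
within its credible interval of the truth; the acceptance suite runs
the recovery at n = 400 with replicate cohorts, where the bias of the
posterior mean is below 0.05 across true m² of 0.10–0.40.
`summary(fit)` adds variance components, fixed-effect posteriors,
effective sample size and split-R̂; `coef`, `fitted`, `residuals` and
`plot` (trace + density) behave as for any fitted-model object.

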