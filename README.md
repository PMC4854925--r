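# epidrift

Analysis of age-related DNA methylation drift and erosion in array-based
methylomes.

Human epidermis is an unusually homogeneous tissue, which makes it a clean
model for asking how the methylome ages: which CpG probes change between
young and old donors, how accurately methylation predicts chronological
age, whether some changes happen as discrete steps at particular ages
rather than gradually, and whether the *patterning* of methylation — its
dynamic range, the similarity of neighboring CpGs, and the similarity
between individuals — erodes with age. `epidrift` implements this analysis
suite for Infinium-style beta matrices (probes × samples), together with a
synthetic-cohort generator that plants each class of age effect with a
ground-truth table, so every stage is verifiable end to end.

## What it computes

- **Differential methylation** between age groups: per-probe linear model
  on M values (M = log2 β/(1−β)) with empirical-Bayes variance moderation —
  prior df `d0` and prior variance `s0²` from moment-matching of log
  residual variances, posterior variance `(d0·s0² + dg·s²)/(d0+dg)`,
  moderated t on `d0+dg` df — Benjamini-Hochberg adjustment, Δβ effect
  sizes, island/shore/shelf/open-sea substructure summaries, and
  LAD-probe means.
- **Age prediction**: leave-one-out or k-fold cross-validated linear
  support-vector regression over all probes, with fold-internal
  standardization, plus a matched-n subsampling protocol for comparing
  methylation against expression predictors.
- **Discontinuous changes**: top-2000 most-variable probe selection,
  subsampled k-means consensus clustering (B=1000, item fraction 0.8),
  mean±SD interval classification of age dependence, and a depth-one
  regression-tree scan per probe (exhaustive threshold search, relative
  error ≤ 0.75 retention, 5-year age bins, CpG-island fractions per
  direction).
- **Erosion**: intra-methylome variance (per sample, across probes) and
  inter-methylome variance (per probe, within group) of M values; median
  |Δβ| of group-mean betas for probe pairs within 1000 bases as a function
  of distance, smoothed by locally weighted regression; pairwise sample
  correlation block means (young–young, old–old, between).
- **Co-expression connectivity**: pairwise Pearson correlation densities of
  the top 30% most-variable genes per age group, transcriptome-wide or
  restricted to gene sets (GMT), with mean |r| and the fraction of
  effectively uncorrelated pairs per group.
- **Synthetic cohorts**: `generate_methylome_cohort()` /
  `generate_expression_cohort()` plant drift slopes, methylation steps,
  age-independent variability, spatially structured baselines, and an
  age-interpolated erosion model (dynamic-range compression `s`,
  inter-individual noise multiplier `h`), returning a truth table for
  parameter-recovery testing.

## Worked example

```r
library(epidrift)

cf <- synth_config(n_probes = 5000, age_design = "two_group", seed = 1)
cohort <- generate_methylome_cohort(cf)

beta   <- filter_probes(cohort$beta, cohort$annotation, cohort$mask)
groups <- factor(cohort$samples$group, levels = c("young", "old"))

fit <- moderated_t_test(beta_to_m(beta), groups)
summary(fit)
#> 1736 of 5000 probes at adjusted p < 0.01 (1227 hyper / 509 hypo)
#> median |delta beta| among significant: 0.0919

methylome_variances(beta_to_m(beta), groups)
#> <erosion_variances> intra-methylome variance by group:
#>   median young: 6.473   median old: 4.121   rank-sum p = 3.06e-09

cv_age_prediction(beta, cohort$samples, scheme = "loo")
#> <age_prediction> 48 samples, scheme=loo (48 models)
#>   Pearson r = 0.999, Spearman rho = 0.995, MAE = 3.60 years
#>   R^2 = 0.997, slope(predicted ~ age) = 0.839
```

The default generator plants small drift and step effects in ~10% of probes
and an erosion gradient (`s = 0.8`, `h = 2` at the oldest age), so: a
minority of probes reach adjusted p < 0.01 with mostly small Δβ (median
≈ 0.09); old samples show lower intra-methylome variance (the dynamic-range
compression); and the planted age signal supports accurate leave-one-out
age prediction with a regression slope below 1, the usual shrinkage
signature of a cross-validated predictor.

A full configuration-driven run (`run_pipeline()`) executes
filter → DMP → prediction → changepoints/consensus → erosion → co-expression
and writes per-stage TSV tables plus a `manifest.json` with versions, the
master seed, a parameter echo, and MD5 hashes of every output; identical
configs and seeds reproduce identical files. A thin command-line wrapper is
installed at `inst/scripts/epidrift`.

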