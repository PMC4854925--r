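---
title: "Methods: models, parameters, and design choices in epidrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in epidrift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`epidrift` analyses array-based DNA methylation cohorts that span the adult
age range, asking four questions about the aging methylome: which probes
change with age (differential methylation), how well methylation predicts
chronological age, whether some changes are step-like rather than gradual,
and whether methylation patterning and transcriptional connectivity erode
with age. Every stage can be exercised on synthetic cohorts with planted
effects, so the whole pipeline is verifiable without access to a real array
dataset.

## Data model and scales

Methylation is carried as a probes x samples matrix on either the beta scale
(proportion methylated, in $[0,1]$) or the M scale, $M = \log_2 \beta/(1 -
\beta)$. Group comparisons are performed on M values, which are closer to
homoscedastic; effect sizes are reported as $\Delta\beta$ (difference of
group mean betas), the conventional unit for array methylation.

The beta-to-M transform uses the pure logit with clipping at
$[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-3}$ by default. No
offset is added (some preprocessing stacks add a small count offset
instead); the clipping bound is recorded on the returned object and
`m_to_beta()` inverts the transform exactly on clipped values. Betas of
exactly 0 or 1 do not occur in normalized array data but can occur in
synthetic data, which is why the bound exists. Missing values are rejected
rather than imputed: every downstream statistic assumes complete matrices.

Probe filtering removes probes on sex chromosomes, cross-reactive probes,
probes with a SNP within five bases of the single-base extension site, and
probes failing detection in at least one sample. Detection failures arrive
as a precomputed boolean mask because computing detection p-values needs raw
intensities, which are out of scope. A probe failing several criteria is
removed once but counted under each criterion.

## Differential methylation

Per probe, a two-group linear model is fitted to M values and the residual
variances $s_g^2$ (on $d_g$ degrees of freedom) are shrunk toward a pooled
prior with the standard empirical-Bayes hierarchical model: assuming
$s_g^2 \mid \sigma_g^2 \sim \sigma_g^2 \chi^2_{d_g}/d_g$ and
$1/\sigma_g^2 \sim \chi^2_{d_0}/(d_0 s_0^2)$, the prior parameters are
estimated by matching the first two moments of $\log s_g^2$, which requires
inverting the trigamma function (done by Newton iteration). The posterior
variance is

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},$$

and the moderated t-statistic $\Delta m / (\tilde s_g \sqrt{1/n_1 + 1/n_2})$
is referred to a t distribution on $d_0 + d_g$ degrees of freedom. Residual
variances of exactly zero are floored at $10^{-12}$ before the log-moment
step. The limits behave as expected and are tested: $d_0 \to 0$ recovers the
ordinary equal-variance t-test, $d_0 \to \infty$ a normal-theory statistic
with the pooled variance. The test suite checks the implementation against
an independently coded oracle (different inversion algorithm) and against
limma to $10^{-8}$ relative precision.

Raw p-values are adjusted by Benjamini-Hochberg step-up (via
`stats::p.adjust`), and probes with adjusted $p < 0.01$ are called
differentially methylated by default. One caveat we document rather than
hide: because $\Delta\beta$ is a difference of group means of a nonlinear
transform of M, its sign can disagree with the sign of $\Delta m$ for
effects of negligible size; for $|\Delta\beta| > 10^{-3}$ the signs agree in
all tested data.

Substructure summaries compare island/shore/shelf/open-sea classes between
groups with a two-sided Wilcoxon rank-sum test on per-sample class means
(the test is not named in typical reports of this analysis; the rank-sum
test is robust to the strongly non-normal distribution of class means), and
DMP enrichment per class uses a chi-square goodness-of-fit against the
array-wide class fractions.

## Age prediction

Chronological age is predicted by linear-kernel $\varepsilon$-insensitive
support-vector regression over all supplied probes, with leave-one-out or
stratified k-fold cross-validation. Features and the age target are
standardized with training-fold statistics only; zero-variance features are
zeroed, so all-constant features can never influence predictions (tested).
Hyperparameters are not prescribed by the analyses this package follows, so
the defaults are the conventional $C = 1$ and $\varepsilon = 0.1$ on the
standardized target; both are configurable. Standardization itself is a
choice: linear SVR on raw betas is scale-sensitive, and we standardize and
say so. Reported metrics include both Pearson and Spearman correlation
(reports of this analysis are often ambiguous about which "$\rho$" is
meant), MAE in years, $R^2$, and the regression slope of predicted on
chronological age, whose shrinkage below 1 is a useful diagnostic of
underfitting. A matched-n subsampling protocol supports fair comparisons
between platforms with different sample counts (methylation vs expression).

## Discontinuous changes

The most variable probes (top 2000 by beta SD, ties broken lexicographically
for determinism) are screened for step-like changes by a depth-one
regression tree: an exhaustive scan over thresholds at midpoints between
consecutive distinct ages, minimizing the post-split SSE subject to at least
`min_branch = 5` samples per side, with ties broken toward the youngest
threshold. The relative error is post-split SSE over root SSE; probes with
relative error at most 0.75 are retained. `min_branch` is our addition:
unconstrained splits at the age extremes are degenerate (a single outlying
sample can absorb the split), and 5 samples per side is the smallest branch
for which a branch mean is meaningfully estimated at this noise level. The
split age is reported as the midpoint between the flanking distinct ages --
a tree package would report the same threshold -- and retained records are
binned in 5-year windows (the granularity of the cumulative count heatmap
is a presentation choice). Probes are classified age-dependent when the
young and old mean $\pm$ SD intervals are disjoint, with a shared endpoint
counting as overlap.

Consensus clustering follows the standard subsampled k-means recipe: 1000
iterations, item subsampling 0.8, feature subsampling 1.0, co-clustering
counts normalized by co-sampling counts, and final assignments from
average-linkage hierarchical clustering of one minus the consensus matrix.

## Erosion metrics

Intra-methylome variance is the variance of M values across probes within
one sample (the dynamic range of that methylome); inter-methylome variance
is the per-probe variance across a group's samples. Both use the unbiased
$(n-1)$ convention, a choice we document because the source analyses do not
specify it. Group differences in intra-variance use a two-sided rank-sum
test. The spatial decay curve enumerates same-chromosome probe pairs within
1000 bases, computes per pair the absolute difference of group-mean betas,
takes the median per distinct distance and smooths it by locally weighted
regression (span 0.3); the young/old difference is tested by a paired
signed-rank test over shared distances. Pair differences use group-mean
betas (not per-sample differences averaged afterwards); the alternative
reading exists, and the choice is recorded here. Exact reproduction of any
particular published p-value is not expected: the underlying tests are
unnamed in such reports, and ours are documented choices.

## The synthetic cohort generator

The generator emulates the structure the analyses assume: 108 female donors
(24 young aged 18-27, 24 old aged 61-78, 60 spanning 20-79) and bimodal
probe baselines (low mode ~0.12, high mode ~0.85) organized into low/high
methylation domains that persist along the chromosome (~5 kb), with island
probes preferentially in low domains. Per probe $i$ and sample $j$, the
noise-free beta-scale profile is

$$c_{ij} = \mu_i + \text{effect}_i(\text{age}_j) + L(\text{pos}_i) +
F_j(\text{pos}_i),$$

where the effect is 0 (null), $\text{slope} \cdot (\text{age} - 40)$
(drift), or $\text{step} \cdot 1[\text{age} \ge \tau]$ (changepoint);
$L$ is a shared smooth landscape (SD 0.015) and $F_j$ a per-sample smooth
random field (SD 0.015), both with a 500-base autocorrelation length, so
short-range beta similarity decays with distance. Erosion then compresses
the profile toward the cohort grand mean, $c \leftarrow \bar m + s(\text{age})
(c - \bar m)$, with $s(\text{age})$ interpolating linearly from 1 at the
youngest observed age to $s$ at the oldest (the linear form is our choice;
only the qualitative old-age endpoint is specified by the model being
emulated), and the profile is clipped to $[\varepsilon, 1-\varepsilon]$.
Finally, inter-individual noise is added on the M scale with a per-entry SD
scaled by the delta-method factor $1/(\ln 2 \cdot c(1-c))$, so that the
induced beta-scale SD equals `noise_sd_beta` $\cdot\, h(\text{age})$ with
$h$ interpolating 1 to $h$. This construction keeps M values exactly
Gaussian per probe -- so the moderated t's type-I behaviour can be tested
cleanly -- while making the configured noise directly interpretable on the
beta scale (verified by simulation to within 10%).

Two design details matter for parameter recovery. First, erosion compresses
the noise-free profile and the noise rides on top: compressing the noise as
well would make old group means less jittery and would invert the expected
ordering of the young/old spatial decay curves. Second, changepoint and
drift baselines are drawn at intermediate methylation (hyper effects start
near 0.2, hypo near 0.7) so planted steps are not distorted by clipping;
group-mean recovery of the planted $\Delta\beta$ within 3 standard errors is
a tested invariant. Erosion magnitudes are not quantified anywhere in the
emulated analyses; the defaults $s = 0.8$, $h = 2$ were chosen once so that
the erosion contrasts are clearly detectable at $n = 24+24$, and the type-I
and null-calibration checks disable erosion entirely ($s = 1, h = 1$),
since erosion makes every probe age-dependent by construction.

The expression generator plants co-expression modules with a single-factor
model per group: standardized expression $= \sqrt{r} f + \sqrt{1-r}
\epsilon$, giving population pairwise correlation $r_{\text{young}}$ or
$r_{\text{old}}$ within the module. Module correlations are restricted to
$[0, 1)$: the single-factor construction cannot produce uniformly negative
pairwise correlations (infeasible beyond $r = -1/(\text{size}-1)$). Module
genes receive larger spreads so that variance-based gene selection retains
them. Values are on an arbitrary log2-like intensity scale; the
co-expression analysis accepts whatever scale it is given and its results
are invariant to per-gene positive affine rescaling (tested).

What the generator does **not** emulate: batch effects, cell-type
composition, sex chromosomes, probe-type chemistry differences, genuine
genomic annotation (islands and LADs are synthetic labels), or raw
intensities and detection p-values. Passing tests on synthetic cohorts
therefore demonstrate the correctness and calibration of the statistical
machinery under the generative model, not robustness to the technical
artifacts of real arrays.

## Problem sizes and numerical choices

The test suite and the acceptance script run cohorts of 400-20,000 probes
and 48-108 samples; these sizes were chosen as the smallest at which each
property is comfortably identified (e.g. type-I calibration uses 20,000 null
probes for a stable rejection fraction, changepoint recovery uses 1000
planted and 1000 null probes). The full 450k-probe scale is a configuration
choice, not a code path change. Deterministic behaviour under a fixed seed
is tested end-to-end (hash-identical pipeline reruns); per-stage seeds are
derived from one master seed. Tie-breaks are always deterministic:
lexicographic probe ids for equal SDs, youngest threshold for equal split
SSEs. Degenerate inputs have defined behaviour rather than errors where a
value makes sense: constant probes get $t = 0, p = 1$; constant-beta probes
get relative error 1 and are never retained; zero-variance samples are
excluded from correlation block means with a warning.

## Known limitations

- The two-group contrast has no covariate adjustment; a general design
  matrix is out of scope.
- The consensus matrix's final assignment depends on average-linkage
  hierarchical clustering; for diffuse consensus matrices (pure noise) the
  assignment is arbitrary, which is the expected behaviour.
- The spatial decay difference test treats distances as exchangeable paired
  observations; distances with few pairs contribute noisy medians, which is
  why assertions about curve ordering are made on the smoothed curves.
- The age-dependence interval rule is deliberately simple (mean $\pm$ SD
  disjointness) and inherits its sensitivity to group SD estimates at small
  $n$.
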