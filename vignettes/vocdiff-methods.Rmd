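---
title: "Methods: the integrative VOC differential test and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the integrative VOC differential test and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Untargeted SPME-GC-TOF-MS profiling of urine headspace yields a peak table:
on the order of a hundred volatile organic compound (VOC) peaks quantified
across two small groups of samples (typically 10 cases vs 10 controls),
with intensities in arbitrary instrument units, spanning orders of
magnitude, and with substantial missingness concentrated in low-abundance
peaks (limit-of-detection censoring). `vocdiff` implements the full
statistical path from such a table to a ranked list of differential
metabolites with false-discovery-rate estimates, plus the companion
microarray analysis used to interpret candidate compounds in cell models.

# Pre-processing

Three operations, applied as `detection_filter()` then `mtic_normalize()`:

* **Detection filter.** A peak is kept only if it was quantified in *more
  than half* of the samples of *each* group — a strict inequality, so with
  10 samples per group a peak needs at least 6 observations in both. The
  filter guards the downstream tests against features whose group
  comparison would rest on a handful of values.
* **mTIC normalization.** Each sample's observed intensities are divided
  by that sample's *mTIC* — the sum of peak intensities over all
  identified metabolites — expressing each peak as a fraction of the
  sample's total volatile metabolome and removing per-sample scale
  (injection/extraction efficiency). Missing cells are excluded from the
  sum rather than zero-filled: a censored value is unknown, not zero, and
  zero-filling would distort the denominator exactly for the samples with
  the most censoring. Missing cells stay missing.
* **Quantile normalization** (`quantile_normalize()`) is provided as a QC
  transform — classic rank-mean normalization (via limma), after which all
  samples share one sorted value vector, with ties receiving the mean of
  the reference values at the tied ranks. It is *not* part of the default
  testing path: the analysis normalization is mTIC, and quantile
  normalization is reserved for quality assessment. It deliberately
  refuses tables with missing cells instead of imputing.

The order — filter, then mTIC, then testing — keeps the normalization
denominator defined on the same peak set for every sample while using only
peaks reliable enough to test. mTIC sums differ slightly between the
filtered and unfiltered table; we normalize after filtering so that the
reported relative abundances refer to the analyzed peak set.

# The integrative hypothesis test

For each peak, three two-sample statistics are computed on the observed
values (missing values omitted pairwise):

* the **Welch t statistic** (unequal variances; the permutation null makes
  the equal-variance/Welch choice second-order, and Welch is the safer
  default at n = 10 per group);
* the **log2 median ratio**, `log2(median(case)/median(control))` — the
  literal reading of the test's name; medians of mTIC-normalized
  intensities are positive, so the ratio is defined;
* the **Wilcoxon rank-sum** statistic.

## Permutation nulls

The null distribution of each statistic is estimated by permuting group
labels over the observed values of the peak. When the number of distinct
case/control assignments `choose(n, n_case)` is at most the
`exhaustive_threshold` (default 20000, so designs up to about 6+6), all
assignments are enumerated and the exact two-tailed proportion
`#{|T| >= |T_obs|}/N` is returned. Otherwise `n_permutations` assignments
(default 10000) are sampled and the add-one estimate
`(1 + #{|T_b| >= |T_obs|})/(B + 1)` is used, which can never return 0. A
10 vs 10 design has `choose(20, 10) = 184756` assignments and is sampled.
One permutation set per peak drives all three statistics, and all
permutation streams are derived deterministically from the configuration
seed, so results are exactly reproducible.

Two numerical details: statistics that degenerate to `0/0` on constant
data are defined as 0 (giving p = 1), and tail counting uses a relative
tolerance of `1e-12` so that analytically tied permutations are not split
by floating-point noise.

## Stouffer combination and its calibration

Each two-tailed p is converted to a signed z,
`z_i = sign_i * qnorm(1 - p_i/2)` with the sign taken from the component's
own effect direction (mean difference, median log-ratio, centered rank
sum), and the three are combined with equal weights:
`z_comb = (z_t + z_lmr + z_w)/sqrt(3)`. Concordant directions reinforce;
discordant directions cancel. `stouffer_combine()` exposes this closed
form, including the Gaussian back-transform `2*(1 - pnorm(|z_comb|))`.

The closed form alone, however, would overstate significance here. The
`sqrt(3)` denominator presumes independent components, while the three
tests run on the *same* values and are strongly positively correlated
(for near-normal data the t/rank-sum correlation is around 0.95); the
variance of `z_comb` under the null is then well above 1 and the nominal
level is badly exceeded (analytically, roughly a 20% type-I rate at a 5%
nominal level). `differential_analysis()` therefore calibrates the
combination against its own permutation null: for every permuted data set
the same recipe is applied — each permuted statistic receives a rank-based
two-tailed p *within the permutation set*, is converted to a signed z, and
the three are combined — yielding the empirical null of `z_comb`, and the
reported `p_adjusted` is the two-tailed permutation p of the observed
combined z in that null. This is the "empirical distribution" reading of
integrative hypothesis testing, and the package's validation suite checks
the consequence directly: under a simulated global null the combined test
rejects at 5% within Monte-Carlo error, and its power at the planted
effect size matches the closed-form noncentral-t oracle.

The reported per-component `p_wilcoxon` column uses the exact rank-sum
distribution (enumeration when both groups are small and untied, normal
approximation with tie and continuity correction otherwise); inside the
combination the rank-sum component uses the same permutation-based p as
the other two components, for internal consistency of the calibrated null.

## Storey q-values

False discovery rates are estimated from `p_adjusted` across all tested
peaks with the single-lambda Storey estimator:
`pi0 = min(1, #{p > 0.5} / (0.5 m))`, floored at `1/m`, and
`q_(i) = min_{j >= i} pi0 * m * p_(j) / j`, capped at 1. The single
`lambda = 0.5` point estimate (rather than a spline over a lambda grid)
was chosen for reproducibility and robustness at the small feature counts
typical of VOC panels (m on the order of 100, where the spline fit is
noisy); with `pi0 = 1` the estimator reduces exactly to
Benjamini–Hochberg, a cross-check the test suite enforces to 1e-12.

## Effect-size columns

`fc_log2` is `log2(mean(case)/mean(control))` on mTIC-normalized
intensities, and `sd` is the pooled standard deviation of the log2
intensities across both groups. Pooled log2 SD was chosen over per-group
or fold-change SDs because it is the scale on which the planted effects
and the power calculations live (`d = |fc_log2|/sd`); the helper
`fold_change_sd()` isolates the computation so an alternative convention
is a one-line change.

Peaks with fewer than two observed values in a group are reported as
untestable with the reason code `insufficient_observations` — they remain
in the output and are excluded only from the q-value computation.

# The synthetic-data generators

`generate_voc_study()` emulates the statistical structure the test
assumes, not the chromatography:

* per-peak log2 mean intensities uniform on [10, 20] (peaks spanning
  roughly three orders of magnitude, as in untargeted GC-MS);
* log2 intensities Normal(mu_j, sigma_log2) per peak, i.e. log-normal
  intensities — the conventional model for peak areas;
* a fraction `frac_differential` of peaks receives a constant shift
  `effect_log2` in the case group; the defaults (10 vs 10 samples, 113
  peaks, effect −1.467, sigma 1.381) mirror the design and the strongest
  reported urinary compound of the study this package models, with a
  negative sign meaning lower in cases;
* per-sample scale factors log-uniform on
  `[1/(1+scale_jitter), 1+scale_jitter]` (default 0.25), so mTIC
  normalization has real work to do;
* missingness from two mechanisms: per-peak left-censoring at the peak's
  `lod_quantile` quantile (default 0.2) — the dominant GC-MS mechanism,
  low-abundance censoring — plus independent random dropout at
  `missing_rate` (default 0.05). The study does not report its table's
  missingness rates, so these two defaults are field-plausible choices,
  fixed once. All draws happen in a fixed order before censoring is
  applied, so under one seed raising `lod_quantile` only ever adds
  missing cells.

`generate_expression_study()` does the analogous job for the microarray
side: per-probe baselines uniform on [4, 12] log2 units, Normal noise
(default sigma 0.25, a typical residual SD for replicate arrays), and DE
probes shifted by `effect_log2` in one designated condition at n = 3
replicates per condition.

What the generators do *not* emulate: retention-time drift, co-elution and
deconvolution artifacts, batch effects, heavy-tailed or peak-dependent
noise, correlated metabolite modules, and probe-to-gene multiplicity.
Passing the simulation suite therefore demonstrates the statistical
machinery is correct under the stated model, not that real studies meet
that model.

One consequence worth stating plainly: left-censoring truncates the lower
tail of case-group intensities for down-regulated peaks, so realized
fold-change estimates are attenuated toward zero relative to the planted
effect (about −1.0 observed for a planted −1.467 at the default 20%
censoring), and discovery counts at q < 0.1 under the default synthetic
conditions are correspondingly conservative — typically zero to a few
peaks per run, fewer than the original study reported on its real data.

# Validation problem sizes

The shipped validation suite runs entirely on generated data at desk
scale: 100-peak tables at 10 vs 10 with 1000 permutations and 100
replicates for the type-I, FDR-control and power checks (power compared
against the closed-form noncentral-t oracle at `d = 1.467/1.381`);
exhaustive-vs-sampled agreement at 5+5 with B = 5000; brute-force
Wilcoxon enumeration up to 6+6; 500-probe expression tables over 200
replicates for DEG recovery. `scripts/acceptance.R` recomputes the same
operating characteristics from scratch under a caller-supplied seed.

# Annotation and enrichment

`validate_cas()` enforces the CAS registry checksum (weighted sum of the
digits, right to left, modulo 10). `map_cas_to_kegg()` is a local join
against a bundled or user-supplied mapping table — deliberately not a web
service, so runs are reproducible; the bundled pathway table is
synthetic/illustrative and KEGG-version-dependent funnel counts are not
treated as reference values. `gobp_enrichment()` uses the one-sided
hypergeometric tail (identical to one-sided Fisher), selecting terms at
raw p < 0.05 with at least 3 DEGs; a Benjamini–Hochberg column is emitted
for information only, since the selection rule of the modeled study uses
the raw p. The default enrichment background is the abundance-filtered
probe set — the universe that was actually eligible for DEG calls.

# Known limitations

* The calibrated combined p is bounded below by `1/(B+1)`; with the
  default B = 10000 and a hundred peaks, attainable q-values bottom out
  near `pi0 * m / (B+1)` divided by the rejection rank, which matters if
  very small FDRs are needed — raise `n_permutations` accordingly.
* Storey's single-lambda pi0 is noisy for very small m; for m = 1 it
  degenerates (floored at 1/m) and q equals p.
* No covariate adjustment, paired designs, multi-group VOC comparisons,
  imputation, or batch correction; probe-to-gene collapsing is out of
  scope for the enrichment stage.
* The Wilcoxon exact path requires untied data; mTIC-normalized
  intensities are continuous, so ties essentially only arise from
  artificial inputs, where the corrected normal approximation takes over.
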