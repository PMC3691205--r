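---
title: "Seminal-plasma CE-MS peptide biomarker discovery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seminal-plasma CE-MS peptide biomarker discovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cemarker)
library(dplyr)
```

## The problem

Capillary electrophoresis coupled to mass spectrometry (CE-MS) profiles the
naturally occurring peptides of a body fluid in a single run: every detected
peptide is characterized by its charge-deconvoluted monoisotopic mass (Da),
its CE migration time (min), and a signal amplitude. Seminal plasma is an
attractive fluid for prostate-cancer biomarker work — it is proximal to the
gland and dominated by proteolytic fragments of semenogelins and other
prostate-derived proteins — but turning raw per-sample peak lists into a
validated diagnostic panel requires a long chain of processing: quality
control, mass/time calibration, amplitude normalization, cross-sample
peptide matching, differential testing, margin-classifier training with
precision-derived cut-offs, and diagnostic evaluation. `cemarker`
implements that chain as composable, pipe-friendly functions, together with
a synthetic cohort generator so every stage is testable end to end without
access to any patient data.

## The synthetic cohort generator

`cohort_config()` + `generate_cohort()` simulate raw (uncalibrated,
unnormalized) peak lists with known ground truth. The defaults encode the
study conditions the pipeline is designed for:

* group sizes 22 PCa, 9 BPH, 14 CP, 5 HC (a 50-sample discovery cohort);
  the two-panel experiments use the full 125-sample design (70/21/25/9)
  split into this training set and a 75-sample test set;
* ~1,800 background peptides, log-uniform in mass over 802.4–15,701.8 Da,
  uniform in migration time over 19–45 min;
* 46 internal-standard peptides present in >97% of samples, and 14 spiked
  calibrant peptides of known coordinates present in every sample;
* amplitudes drawn log10-normally around per-peptide baselines
  (`base_amplitude_mean = 2.5`, `base_amplitude_sd = 0.5`);
* missing values coded 0, produced by an amplitude-dependent logistic
  dropout (lower amplitude, higher dropout) on top of a baseline
  `missing_rate`;
* per-sample distortions for the calibration stage to undo: a
  multiplicative mass error (SD 25 ppm — half the small-peptide clustering
  tolerance), an affine migration-time error (offset SD 0.3 min, gain SD
  0.01), and a global log10 amplitude shift (SD 0.2) representing dilution
  and ionization efficiency.

Two noise choices deserve justification, since no amplitude distribution is
published for this kind of data:

* **Per-peak amplitude noise** defaults to 0.15 log10 units (~35% CV). We
  calibrated this against the study design the generator emulates: its
  weakest reported markers (regulation ratios of 1.2–1.8) are
  BH-significant in a 22-vs-28 rank-sum comparison, which is only possible
  if within-group log10 variability is well below 0.2. A noisier setting
  (0.25) makes such effects undetectable at these sample sizes.
* **Internal standards** get a lower per-peak noise (0.08 log10) and a 0.3
  log10 spread of baselines: they are, by construction, peptides selected
  for abundance and signal stability.

Planted differential markers are specified per group as a log10 amplitude
shift plus a detection frequency, and always occupy exactly one background
peptide slot. `reference_marker_config()` converts the bundled 21-marker
reference table into such a configuration, reproducing the published group
mean ratios in expectation. Ground truth (marker slots, standard
identities, per-sample distortions) is emitted alongside the data and never
read by any pipeline stage.

What the generator does **not** emulate: isotope envelopes, charge states,
correlated peptide families (e.g. fragments of one parent protein rising
and falling together), batch effects, or age/PSA confounding. Passing
recovery tests on synthetic cohorts therefore demonstrates that the
pipeline is correct and well-calibrated under its stated error model — not
that the biological panels would validate in new patients.

## Calibration and normalization

`calibrate_profiles()` matches reference peptides to observed peaks within
a coarse window (±200 ppm, ±3 min) and corrects masses by a single global
linear map and migration times by piecewise-local linear maps — overlapping
windows of width one fifth of the time range with 50% overlap, blended with
triangular weights, falling back to the global fit where a window has fewer
than two points. Both fits discard points with residuals above 3×MAD in one
re-fit pass. Calibration changes only coordinates, never peak counts, and
the post-calibration mean absolute time deviation against the references is
recorded per sample (the QC criterion requires it below 0.30 min).

`normalize_amplitudes()` removes per-sample amplitude distortions using the
internal standards. The correction is the local-linear regression of the
standards' log10(observed/reference) ratio on migration time — local when
at least 5 standards fall in a window, global otherwise — subtracted from
every peak's log10 amplitude. Reference amplitudes default to each
standard's cohort geometric mean. We deliberately did *not* regress
observed on reference amplitude across standards: with standards spanning a
narrow amplitude range that is an errors-in-variables regression whose
slope collapses toward zero and destroys biological signal; a
time-dependent log-ratio offset is the standard internal-standard scheme,
is idempotent, recovers a global scale factor exactly, and is strictly
monotone in amplitude at any migration time.

## Cross-sample clustering

Peptides in different samples are considered identical when their mass
deviation is within 50 ppm for small peptides (strictly below 4,000 Da) or
75 ppm for larger ones, and their migration times fall within a window
whose full width grows linearly from 2% of migration time at 19 min to 5%
at 45 min (diffusion broadens CE peaks over the run; the width is read as a
fraction of migration time, half-width = fraction × time / 2).

`cluster_profiles()` assigns peaks greedily in order of descending
amplitude (ties broken by mass, time, then sample id, so the partition is
invariant under sample relabelling): each unassigned peak seeds a cluster,
and a peak joins an existing cluster iff it passes both tolerance tests
against the cluster's consensus and its sample is not yet represented.
The consensus used during assignment is frozen at the seed peak's
coordinates — this keeps the algorithm order-independent — while the
reported consensus is the amplitude-weighted member mean. Eligible-cluster
ties go to the smallest ppm deviation, then the smallest time difference.
On instances where peptides are well separated relative to the tolerances,
this greedy partition coincides with the all-pairs
connected-components oracle, which is the correctness surface the tests
use. `filter_sporadic()` then keeps only clusters detected in at least 7
samples ("more than 6") of at least one diagnostic group.

## Differential testing

Candidates must be detected in at least 60% of one comparison group
(`frequency_filter()`, inclusive boundary). Group comparison uses the
two-sided Wilcoxon rank-sum test in its normal approximation with mid-rank
ties, tie-corrected variance and continuity correction
(`rank_sum_test()`); undetected measurements enter as zeros, i.e. the
smallest tied block — no imputation. Because the test is rank-based, the
log10 transform conventionally applied to intensities does not change the
p-value; the tests assert this invariance. Benjamini–Hochberg step-up
adjustment (`bh_adjust()`, delegating to `stats::p.adjust`) controls the
FDR across clusters; the candidate threshold defaults to adjusted p ≤ 0.10,
chosen because the reference marker table retains peptides with adjusted p
up to 0.098. Group means are computed over detected values only (matching
how the reference table's large means coexist with sub-100% frequencies),
and the signed regulation ratio is `mean_case/mean_control` when the case
mean is at least the control mean and `-mean_control/mean_case` otherwise,
reported to one decimal. BPH-specificity screening is expressed as three
`discover_markers()` calls plus `intersect_markers()`.

## Panel classification

`train_panel()` fits a linear soft-margin SVM (`e1071::svm`, cost 1 — the
original classifier's settings are unpublished) on log10 member amplitudes.
Undetected panel members are imputed as half the member's smallest detected
training amplitude; features are centered and scaled by training statistics
using the population (denominator-n) SD, so a two-point problem
standardizes to ±1 and reproduces the closed-form maximal-margin solution.
The classification score is the signed Euclidean distance to the hyperplane
(positive toward the designated positive class), invariant to rescaling of
the weight vector.

Diagnostic cut-offs shift an operating threshold by one
analytical-precision SD (`derive_cutoff()`): under a Gaussian error model
this leaves under a 16% chance that a measurement whose true score sits at
the threshold falls on the wrong side. The worked values are 0.30 − 0.30 =
0.00 a.u. for the 21-peptide panel and 1.00 + 0.48 = 1.48 a.u. for the
5-peptide BPH-exclusion panel. The operating threshold defaults to the
midpoint between class median training scores; the published thresholds'
derivation is not described, so the quantity is an explicit input.
`stepwise_diagnose()` applies the two-step rule: below the first cut-off →
control; at/above it and below the second → PCa; at/above both → BPH. The
published wording ("positive in either panels were considered as BPH")
contradicts its own PCa clause if "either" is read literally; we read it as
"both", which is the only reading that makes the rule a total function.
`classify_advanced()` thresholds the advanced-disease panel score at 0.30
a.u., inclusive on the advanced side.

## Evaluation

`confusion_metrics()` reports sensitivity and specificity with exact
Clopper–Pearson 95% intervals (beta-quantile form; verified against a
binomial-tail search), rounding percentages half away from zero — this
reproduces all four published interval bounds for 40/48 and 18/27.
`roc_auc()` uses the pairwise-concordance (Mann–Whitney) AUC with ties at
one half and a stratified bootstrap percentile interval (2,000 resamples).
Replicate precision is summarized as SD divided by the panel's fixed score
range (`cv_over_range()`; scores live on an interval scale, so SD/mean
would be meaningless). `stability_analysis()` pairs Spearman rank
correlation (Fisher-z interval, 1/√(n−3)) with the OLS slope in a.u./hour;
at n = 14 and rho ≈ −0.58 the Fisher-z interval reproduces the reference
interval (−0.854, −0.07) to within 0.01 per bound.

## Numerical and degenerate-input conventions

* QC boundaries follow the stated wording literally: "minimum of 1000" and
  "minimum ... of 10 minutes" are inclusive, "below 0.30 minutes" is
  strict. Identification bounds (±80 ppm, ±2 min) are strict.
* `mass_tolerance(4000)` is 75 ppm ("small" is strictly below 4,000 Da);
  the time-window fraction clamps outside 19–45 min.
* A sample with fewer than 2 matched calibration references, or fewer than
  3 detected internal standards, is an error naming the sample.
* Identical rank-sum multisets give p = 1; a zero variance from complete
  tying gives p = 1. A zero group mean flags "infinite regulation" (NA)
  rather than ±Inf.
* Constant replicate scores make rho undefined (flagged) with slope 0.
* Monoisotopic masses are reported to 3 decimals, ppm deviations to the
  nearest integer, regulation ratios to one decimal — each overridable.

## Problem sizes used in the test suite

Simulation-based tests run at 400 background peptides (recovery loops: 50
discovery seeds, 25 two-panel seeds) and one full-scale 125-sample,
1,800-peptide cohort for the cluster-count check — sizes chosen so the
whole suite completes in a few minutes while keeping every rate estimate
multi-seed. The full-scale defaults remain the generator's.

## A worked example

```{r example, eval = FALSE}
cfg <- cohort_config(n_background_peptides = 400,
                     planted_markers = reference_marker_config())
coh <- generate_cohort(cfg, seed = 42)
refs <- reference_set(coh$calibrants, coh$standards)

tab <- coh$peaks |>
  calibrate_profiles(refs) |>
  normalize_amplitudes(refs) |>
  cluster_profiles() |>
  filter_sporadic(coh$samples)

markers <- discover_markers(tab, coh$samples,
                            case = "PCa", control = c("BPH", "CP", "HC"))
autoplot(markers)
```

## Known limitations

* Clustering is greedy; pathological peak configurations (chains of peaks
  each within tolerance of the next) can split where a global method would
  merge. The brute-force oracle equivalence holds on well-separated
  instances only.
* The published 5- and 11-peptide panel memberships are not fully public;
  panels here take any member list.
* The AUC interval is bootstrap-based, not the DeLong or exact method, and
  the Spearman p-value uses the t approximation — both adequate at the
  sample sizes involved but not exact.
* The generator's independence assumptions (peptides independent given
  group, noise iid) understate the correlation structure of real
  peptidomes; recovery rates on synthetic cohorts are accordingly
  optimistic.
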