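---
title: "densomics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{densomics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(densomics)
```

# Scope

densomics analyses dense, irregularly sampled blood multi-omics time courses
collected by remote microsampling alongside wearable sensor streams (heart
rate, step count, continuous glucose). It covers five analysis families:

1. **Lagged correlation** between an asynchronous sparse series (a blood
   analyte) and a dense series (a wearable stream), with a Gaussian-fit
   quality score and a wearable-molecule network.
2. **Meal-challenge response**: paired screening, permutation-calibrated
   ANOVA, fuzzy temporal clustering, consensus clustering of participants,
   and six AUC-based metabolic scores.
3. **Dense 24/7 profiling**: day-wise LOESS smoothing, day-to-day
   consistency, Lomb-Scargle circadian testing, correlation-network
   community modules, Gaussian peak detection and nutrition association.
4. **Storage-stability QC**: per-analyte regression on storage duration and
   temperature with partial R^2 and LMG variable importance, plus a
   cross-platform median-profile comparison.
5. **Wearable-feature prediction** of analytes by random forests.

A seeded synthetic-data module generates every input with known ground truth
(lags, rhythms, response archetypes, degradation coefficients), so each
estimator is validated by parameter recovery rather than by eyeballing.

# Data model

`OmicsTimeCourse` extends `SummarizedExperiment`: one `values` assay
(analytes x samples), per-analyte `analyte_class`, per-sample `participant`,
`timestamp_min` (minutes since study start) and categorical `timepoint`.
Validity enforces unique ids and strictly increasing timestamps within a
participant. `WearableStream` holds one non-negative, strictly ordered
(timestamp, value) series. `LagScan`, `ScorePanel` and `SmoothedCourse`
carry the results of the corresponding analyses with their own invariants
(symmetric shift grid, scores in [0, 1], constant within-day grid step).

# Preprocessing conventions

* `log2Autoscale` transforms to log2 and standardizes each analyte to mean
  0, sd 1; zero-variance analytes become all-zero and are flagged rather
  than producing NaN.
* `imputeKnn` (k = 10 by default) replaces a missing value with the mean of
  the k nearest analytes (Euclidean distance over mutually observed samples,
  normalized per shared sample; ties broken by row order so results are
  deterministic). Only analytes observed in the target sample qualify as
  neighbours.
* `filterMissingness` uses a *strict* presence threshold: at 0.5, an
  analyte present in exactly half the samples is removed.
* `cvLogScale` computes the natural-scale coefficient of variation from
  log2 data via \(CV = \sqrt{e^{(\sigma\ln 2)^2} - 1}\) per participant and
  averages participants. The formula is validated in the test suite against
  a 100,000-draw lognormal Monte-Carlo (agreement within 2%). Autoscaled
  input is rejected because standardization destroys the scale the formula
  needs.

# Lagged correlation

For a sparse series \(X\) (timestamps \(t_i\)) and dense series \(Y\)
(timestamps \(t_j\)), each trial shift \(T_s\) matches to every \(Y_{t_j}\)
the \(X\) points with \(t_j + T_s - T_w/2 \le t_i < t_j + T_s + T_w/2\),
averaging multiple matches (a sum would be inconsistent across varying
match counts). The Spearman correlation of matched vectors versus shift
forms a curve; the reported lag is the maximum absolute correlation with
sign preserved, and a negative shift means the dense series leads. A
four-parameter Gaussian (amplitude, centre, width, offset) is fitted to the
curve; the *quality score* is the absolute Spearman correlation between
fitted and observed curves. The offset term makes quality invariant to
constant shifts of the curve.

**Effective sample size.** The matching rule reuses one \(X\) window for
every dense point it covers (about \(T_w/\Delta y\) times), so the matched
pairs are partial copies of each other. P-values are therefore computed
from the t approximation at the number of *distinct matched windows*, not
the raw pair count; with the raw count, pure-noise molecules reach
\(p < 0.05\) essentially always and the FDR filter in the network becomes
vacuous. The correlation estimate itself is unaffected.

**Window-choice guidance** (from the recovery experiments in the test
suite): keep the matching window within about two shift-grid steps. A much
wider window smears the peak, and if the dense series has an asymmetric
autocorrelation (CGM meal excursions rise fast and decay slowly) the peak
location can shift by up to about a third of the window. Conversely, the
Gaussian quality score is only informative when the true
correlation-versus-shift bump spans several grid points, which it does when
the analyte integrates its driver over tens of minutes (the physiological
case) or the window is comparable to the bump width. The scan range should
cover the expected lag with modest tails: tails dominated by the driver's
slow autocorrelation pedestal dilute the quality score.

`laggedCorNetwork` screens every (wearable, molecule) pair, adjusts best-lag
p-values by Benjamini-Hochberg within each wearable, and keeps edges with
adjusted \(p < 0.05\) and quality at least `quality_min` (default 0.8;
0.7 is the operating point used in the recovery tests, where the false-edge
count is controlled by the FDR filter and quality only removes misshapen
maxima).

# Meal-challenge analyses

Screening compares each post-shake timepoint (30/60/120/240 min) with
baseline by the paired Wilcoxon signed-rank test ("paired rank-sum" has no
paired form), BH-adjusted within timepoint (a global-family switch exists).
If every paired difference is exactly zero the test is reported as p = 1.
The ANOVA screen is a one-way ANOVA on timepoint, vectorized over analytes
(equality with `stats::aov` is asserted in the tests); its cohort-level
calibration shuffles timepoint labels *within participant* — the weakest
exchangeability consistent with the design — and reports
\(p = (1 + \#\{null \ge observed\})/(B + 1)\) for the observed count of
BH-significant analytes over \(B = 100\) permutations.

Fuzzy c-means uses the dimension-based fuzzifier estimate
\(m = 1 + (1418/N + 22.05)D^{-2} + (12.33/N + 0.243)D^{-0.0406\ln N - 0.1134}\).
On wide grids (hundreds of columns) this estimate approaches 1 (near-crisp
clustering) and soft memberships saturate; the membership-retention filter
(\(\mu > 0.5\)) is then inert, so analyses that rely on it should pin
`fuzzifier = 2`. The cluster number scans 2-22 and takes the first k whose
minimum-centroid-distance decrease falls under 10%; centres correlating
above 0.8 are merged afterwards (memberships summed), which also repairs an
overshooting elbow. Candidate k is capped at the number of distinct
profiles.

Consensus clustering resamples 80% of participants 1,000 times, runs
k-means, and records co-clustering frequencies among co-sampled pairs; the
group number is chosen by the mean silhouette width on `1 - consensus` and
assignments come from average-linkage clustering of that dissimilarity.
When participants are grouped by response *kinetics*, each participant's
baseline-subtracted response vector is normalized to unit length first —
otherwise responder magnitude (a separate, real axis of variation measured
by the metabolic scores) dominates the distance and masks the kinetic
groups.

# Metabolic scores

For each molecule and participant the 5-point profile is baseline-subtracted
and integrated by the trapezoid rule over minutes (0/30/60/120/240); AUCs
are min-max normalized per molecule across participants (zero-range
molecules get 0.5 and a flag); a score is the mean of its panel's
normalized AUCs, inverted (1 - MS) for panels where a large cumulative
excursion means slow clearance (carbohydrate, amino acid, fat, FFA).
Normalization absorbs any per-molecule affine rescaling of raw intensities,
so the scores are unit-free. Participants are grouped by Ward (`ward.D2`)
hierarchical clustering of the score vectors, k = 5 by default. Baseline
outliers are flagged by a robust z-score (median/MAD, threshold 3) on the
first two principal components of the baseline samples; the criterion is
this package's choice.

# Dense profiling

LOESS smoothing is per day (degree 2, tricube), with the span chosen per
molecule by 5-fold contiguous-block cross-validation over {0.3, ..., 0.9},
and predictions on a 30-min grid strictly inside each day's sampled range.
A day boundary is any sampling gap over 4 h, so no fit ever bridges the
night. Days with fewer than 5 points are skipped.

The consistency score is the median Spearman correlation between
time-of-day-aligned day pairs (all pairs, not only adjacent days). The
circadian test is a *floating-mean* (generalized) Lomb-Scargle at the 24-h
period: with waking-hours-only sampling the 24-h sinusoid is strongly
non-orthogonal to the intercept and the classic fixed-mean periodogram is
measurably miscalibrated, while the floating-mean single-frequency null is
exactly \(F(2, n-3)\) for any sampling pattern (the tests verify KS
uniformity on 1,000 null molecules). Scanning a period band applies a Sidak
correction over the scanned frequencies.

Correlation networks connect molecules with Spearman rho > 0.7 and
BH-adjusted p < 0.05; communities come from fast greedy modularity
optimization; module mean courses are scanned for peaks by local-maximum
candidates refined with a windowed Gaussian fit (acceptance: window
R^2 >= 0.8 and amplitude >= 1 sd of the course — both package choices), and
the binary peak indicators are compared against grid-discretized food-log
events by the Jaccard index (retained above 0.3).

# Storage stability

Each analyte is regressed (OLS) on storage duration (h), temperature
(numeric deg C — a single slope and a single interaction term imply numeric
coding), duration x temperature, and a participant indicator. Duration-0
samples were never exposed to a storage temperature and are excluded,
except in the duration-only sensitivity model where they extend the
duration axis. Significance is nominal P = 0.05 without multiplicity
correction — deliberately conservative toward declaring instability.
Partial R^2 is the two-fit definition \(1 - SSE_{full}/SSE_{-term}\); LMG
importance averages each regressor's sequential R^2 increment over all
orderings (computed by subset enumeration with ordering weights; shares sum
to the model R^2 to 1e-8 and equal exhaustive permutation enumeration in
the tests).

# Wearable prediction

For each blood-draw time the trailing window [t - w, t] of each stream is
summarized by eight statistics (mean, median, sd, max, min, skewness,
kurtosis, range; skewness/kurtosis of degenerate segments are 0 and
flagged), giving 24 predictors for three streams. Random forests (500
trees) are evaluated by sevenfold cross-validation with contiguous time
blocks (limiting temporal leakage; a random-fold switch exists) and pooled
out-of-fold \(R^2 = 1 - SSE/SST\); a molecule is "predictable" when any
window in the sweep (5-120 min) exceeds \(R^2 = 0.3\).

# The synthetic cohort

`simWearables` produces: Markov walking bouts (mean ~8 min, 60-120
steps/min) with incidental movement in ~35% of idle waking minutes; heart
rate = 65 bpm + 3 bpm circadian + 0.4 bpm per step/min coupling at a 1-min
lag + 2 bpm noise; CGM = 95 mg/dl with ~40 mg/dl gamma-kernel meal
excursions every 5 min. These defaults reproduce the step-HR lagged
correlation regime (~0.6 at -1 min) that motivates the lag-recovery checks.
`simSamplingTimes` emulates hourly waking-hours self-sampling (06:00-23:00,
+/-15 min jitter), leaving a >4 h overnight gap. `simOmics247` builds
analyte blocks from five mechanisms (circadian sinusoid, gamma meal kernel,
one-compartment kinetics with ~24 h clearance, wearable-driven with a known
lag integrated over a 30-min physiological window, pure noise) on the log2
scale and always returns a ground-truth table. `simShakeCohort` plants
three response archetypes (sharp 60-min peak, gradual late peak,
dip-and-recover) scaled by per-participant responder magnitudes
(uniform 0.6-1.4) and warped by fast/slow kinetic groups; noise defaults to
0.25 of the unit signal. `simStabilityDesign` reproduces the two-donor,
three-temperature (4/25/37 C), six-duration (0-120 h), duplicated design
with per-analyte linear degradation coefficients.

What the generator does *not* emulate: assay batch effects, missingness
mechanisms correlated with intensity, heteroscedastic noise, inter-analyte
correlation beyond the planted mechanisms, or realistic meal composition.
Passing recovery tests therefore demonstrates that the estimators recover
their own generating model at realistic noise — not that real data meet
those assumptions.

# Numerical choices and problem sizes

Convergence and tie-break conventions: c-means runs at most 200 iterations;
KNN neighbour ties break by row order; the best lag takes the first
maximum; Gaussian fits run Levenberg-Marquardt (500 iterations) and
non-convergence yields quality 0 with a flag. The shipped tests and the
acceptance script use deliberately compact problem sizes — cohorts of
28 participants x ~100 analytes, 3-7 day wearable streams at 1-5 min
resolution, 1,000-analyte null panels for calibration checks — chosen so
the full validation cycle runs in minutes while keeping every statistical
check adequately powered (binomial or KS standard errors are quoted in the
tests where they matter).

# Known limitations

* The lagged-correlation scan reports association at a lag, not causality.
* Lag localization is limited by the sparse series' sampling interval;
  hourly omics cannot resolve minute-scale lags no matter the grid.
* The quality score assumes a single dominant lag; genuinely multimodal
  lag structures (e.g. dual-phase responses) will score poorly.
* The storage model is a fixed-effect linear model per analyte; duplicate
  correlation within (participant, condition) cells is not modelled.
* Consensus clustering inherits k-means' spherical-cluster bias.
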