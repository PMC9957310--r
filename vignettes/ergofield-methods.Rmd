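---
title: "Methods: direct workload measures, perceived-exertion scales, and their association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: direct workload measures, perceived-exertion scales, and their association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ergofield)
```

## The problem

Field ergonomics studies of orchard harvesters instrument workers with a
1-Hz heart-rate monitor and bilateral 1000-Hz trapezius surface EMG over a
full work shift (here, 7:30–15:00 with one mid-morning break), and collect
three perceived-exertion instruments at four timepoints (T0 pre-shift, T1
at the start of the break, T2 at the end of the break, T3 at shift end):
the Borg RPE (6–20, overall effort), the Omni RPE (0–10 with pictorial
anchors, overall effort), and the Borg CR10 (0–10, one rating per
shoulder, local tiredness). The scientific question the package
operationalizes is whether the subjective ratings can stand in for the
direct measures: the percent heart-rate reserve as metabolic load, and the
drift of the EMG spectrum as localized muscle fatigue.

`ergofield` implements the full analysis chain plus a synthetic-cohort
generator with known ground truth, so every stage — filtering, spectral
estimation, artifact screening, slope fitting, and the statistical
battery — is testable end to end without any field data.

## Direct measure 1: percent heart-rate reserve

Raw 1-Hz heart rate is cleaned with a 5-point moving median
(`moving_median_filter()`), which removes the isolated spike artifacts
chest-strap monitors produce while preserving level shifts. At the series
edges the window shrinks symmetrically (staying centred and odd) rather
than padding: no data are invented at recording boundaries, and the filter
remains idempotent on monotone stretches.

Period means are taken over schedule-aligned windows (15 min of pre-shift
sitting for T0; the last 10 min of work before the break for T1; the last
10 min of the break for T2; the last 10 min of the shift for T3 — T1 and
T3 deliberately sample *work*, not the survey pause). All windows are
half-open `[start, end)` on a seconds-of-day clock, which avoids
double-counting boundary samples. Means carry a coverage fraction; by
default windows with under 50% of their nominal samples are flagged, not
dropped — the analyst decides.

The reserve is the standard age-predicted normalization,

\[
\mathrm{HR}_{max} = 220 - \text{age}, \qquad
\mathrm{HR}_{rest} = \mathrm{HR}_{sit} - 10, \qquad
\%\mathrm{HRR} = \frac{\mathrm{HR}_{work} - \mathrm{HR}_{rest}}
                      {\mathrm{HR}_{max} - \mathrm{HR}_{rest}},
\]

evaluated exactly by `compute_hrr()`. Values outside `[0, 1]` can occur
with noisy field data and are returned with a flag, never clipped —
clipping would bias group comparisons. Because reserve fractions are
right-skewed, `sqrt_transform_with_normality()` applies the square-root
transform and reports Shapiro–Wilk statistics both before and after, so
the transform's effect is auditable rather than assumed; negative inputs
are excluded from the transform with a reported count. Association
analyses default to the transformed outcome (`hrr_sqrt`), with the raw
fraction available via a config switch, since the transform exists
precisely to meet the normality assumption of the downstream linear
models.

## Direct measure 2: EMG median-power-frequency fatigue slope

Surface EMG is band-passed to 20–450 Hz with a 4th-order Butterworth
applied with zero phase. The implementation multiplies the signal's
spectrum by \(|H(f)|^2\) — the exact transfer of a forward–backward
(filtfilt) pass — in the frequency domain; it agrees with
`signal::filtfilt` to numerical precision away from edges (a unit test
asserts this) and gives ≥ 48 dB attenuation one octave beyond each cutoff
with no edge transients.

Features are computed per non-overlapping 10-minute window: percentiles
(p10/p50/p90) of the rectified amplitude, mean and median power frequency
over the analysis band, and total band power. The power spectral density
is a Welch estimate — 1-second Hann segments at 50% overlap — giving a
stable density at 1 Hz resolution, the standard compromise for surface
EMG. The median power frequency is read from the cumulative band power
anchored at bin centres (each bin's mass spread symmetrically about its
centre) with linear interpolation: equal mass at 100 and 200 Hz yields
150 Hz, and a flat 20–450 Hz spectrum yields exactly the midpoint 235 Hz.
Two conventions for "MPF" circulate — mean versus median power frequency;
the fatigue metric here defaults to the **median** (more robust to the
high-frequency tail), both are always stored per window, and
`mpf_metric = "mnf"` switches the analysis.

Field EMG suffers electrode saturation and strap interference.
`detect_anomalous_windows()` screens the per-window feature matrix per
subject-side: robust standardization (median/MAD), PCA, and a chi-square
test (default 0.999 quantile) on the robust squared distance in the
components covering ≥ 90% of variance. Windows flagged there — plus any
window with no usable spectral content — are excluded from slope fitting.
The threshold and variance fraction are configuration parameters; the
screen is designed to flag gross contamination while rejecting under 1%
of clean windows (and is tested never to reject more than 20%).

Fatigue per subject-side is the ordinary least-squares slope of the
median power frequency on work time,

\[ \mathrm{MPF} = b_0 + b_{Time}\,\mathrm{Time}, \]

fitted by `fit_fatigue_slope()` over non-break, non-anomalous windows
(at least 3 required; otherwise a missing-result row). **Units are
explicit**: Time is minutes of accumulated work since shift start, with
the clock frozen during the break — reported slope magnitudes depend
entirely on this convention, so it is stated in every output.
`pooled_slope_model()` fits `MPF ~ time + side + subject` across the
cohort: the subject fixed effects absorb between-worker spectral levels,
the side term absorbs the dominant/non-dominant offset (the source of the
bimodal pooled MPF distribution), and the time coefficient is the pooled
fatigue slope.

## Subjective measures

`validate_responses()` enforces scale ranges (Borg RPE 6–20, Omni RPE
0–10, CR10 0–10 with half steps tolerated), site conventions, and key
uniqueness, returning rejected rows with reasons. Ratings are analysed as
baseline deltas — the change from the same subject's T0 rating
(`delta_from_baseline()`); a missing baseline yields an explicit missing
record, never an implicit zero. For local discomfort,
`cr10_shift_change()` computes the shift-long (T3 − T0) CR10 change per
shoulder and labels shoulders dominant/non-dominant from the roster. The
Omni RPE numeric range is taken as the standard 0–10 (overridable); CR10
half-point ratings are accepted as conventionally allowed.

## The association battery

`association_battery()` joins the reserve table with the rating deltas on
subject × period and runs, at a fixed 95% confidence level:

* unadjusted Pearson correlations (direct vs subjective);
* linear regressions adjusting for the known confounders — work period
  and harvesting method (treatment coding, alphabetically first level as
  reference);
* the same model stratified by harvesting method (adjusting period) and
  by work period (pooling methods), with strata under 3 complete cases
  reported as missing rows;
* Spearman's rank correlation (mid-ranks for ties) between the two
  overall-effort scales' deltas;
* two-way ANOVA (sequential sums of squares, matching the classic
  `anova(aov(...))` workflow) of the transformed reserve on group and
  period, with Tukey HSD pairwise group comparisons;
* Kruskal–Wallis omnibus tests with Dunn rank-sum post hoc z tests for
  factor effects on the (ordinal) rating deltas. Dunn p-values are
  reported unadjusted by default — matching the common field practice of
  reading the pairwise tests descriptively — with a Holm switch for users
  who want family-wise control. The Dunn statistic is implemented
  directly (tie-corrected rank-sum z), as no installed package provides
  it; unit tests pin it to brute-force rank computation.

Stratified-by-period analyses use deltas (not raw ratings) by default,
because the baseline-referenced change is what makes ratings comparable
across subjects; raw values remain available upstream.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated: 3 harvesting groups × 8 male workers, ages uniform on 18–47,
a 7:30–15:00 shift. The break is configurable with two shipped presets —
a 30-minute rest (`"rest30"`, used throughout the tests) and a long
9:00–10:30 break (`"fullbreak"`) — because field protocols differ on this
point; nothing downstream depends on the choice beyond the window
positions. A compressed `"demo"` day (40-min bout, 15-min break, 30-min
bout) exists for fast end-to-end runs.

*Heart rate* is a piecewise-constant profile — sitting baseline
(mean 72 ± 5 bpm between subjects), plus `hr_gain` (default 60 bpm per
unit exertion) times the period's latent exertion during work — with
Gaussian noise (default 3 bpm) and optional isolated spike artifacts
(default rate 0.002/sample) for median-filter testing. Latent exertion is
drawn per subject and work period on `[0, 1]` with group means 0.45
(Ground), 0.60 (Ladder), 0.40 (Platform) — ladder work hardest, platform
lightest — SD 0.10, a near-rest 0.10 during the break period, and a
+0.05 afternoon uptick. These defaults put simulated reserves in the
0.15–0.75 band typical of sustained harvesting work.

*EMG* is synthesized block-wise: for each 1-second block, complex-Gaussian
Fourier coefficients are shaped by a Butterworth band-pass envelope
(default width 40 Hz) centred at
`intercept(subject, side) + slope(subject) × work-minutes`, and inverse
transformed. This frequency-domain construction is distributionally the
white-noise-through-a-drifting-bandpass model while controlling the PSD
exactly and vectorizing cleanly; the 1-s block length is far below the
10-minute analysis window, so the within-window spectrum is effectively
the programmed one. The centre frequency freezes during the break,
mirroring spectral recovery at rest. Intercepts default to 80 Hz
(population SD 5 Hz) with a +8 Hz non-dominant-side offset — the source
of the bimodal pooled distribution — and the default programmed slope is
−0.01 Hz per work-minute. Parameters that would push the envelope outside
(20, 450) Hz raise an error. `emg_stochastic = FALSE` replaces the random
signal with a deterministic constant-amplitude tone tracking the
programmed centre: the generator's zero-noise limit, in which slope
recovery is limited only by the 1-Hz spectral binning. Contaminated
windows (for screen testing) alternate hard clipping at half the RMS with
strong in-band 30 Hz interference plus sub-band drift, and their indices
are recorded as ground truth.

*Ratings* use a Gaussian copula on the ranks of latent exertion: normal
scores of the pooled exertion values (T0 pinned at 0) are mixed with
independent noise using a weight calibrated — by the generator's own
large-sample simulation with a fixed internal seed
(`calibrate_rating_weight()`) — so the population Spearman correlation
between the discretized rating and exertion equals the programmed
`rating_rank_correlation` (default 0.6). Targeting the rank correlation
directly matches the nonparametric way the ratings are analysed; the
calibration absorbs the attenuation caused by discretizing onto the
integer scales. Each scale and each CR10 shoulder draws independent
noise, so scales correlate with each other only through the shared
latent exertion. The CR10 is driven by exertion and *not* by the EMG
slope, so the CR10-change versus fatigue-slope association is null by
construction — the generator's mirror of a decoupled subjective/direct
pair.

What the generator does **not** emulate: heart-rate variability and
thermoregulatory drift, motion-artifact structure beyond isolated spikes,
non-stationary EMG amplitude (bursts with task rhythm), and
learning/anchoring effects in repeated ratings. Passing tests therefore
demonstrate the correctness of the estimators under the stated model, not
robustness to every field pathology.

## Numerical choices and degenerate inputs

* Clock times are integer seconds of day; windows half-open.
* The median filter requires an odd window; even windows are an error,
  not silently adjusted.
* Welch segments are 1 s with a periodic Hann taper; the one-sided
  density satisfies Parseval to within discretization.
* The median-frequency interpolation rule (bin-centre cumulative) is
  exact for point masses and symmetric two-bin spectra; zero band power
  is an error, and such windows are pre-flagged anomalous instead of
  fitted.
* PCA screening drops constant feature columns with a warning, skips
  subject-sides with fewer than 10 usable windows (pass-through,
  warned), and scales scores by MAD so outliers cannot mask themselves.
* Regression helpers return explicit missing-result rows (never silently
  dropped strata) when `n < 3` or the predictor is constant; aliased
  terms are dropped with a warning.
* All generator functions draw from locally scoped RNG streams derived
  from the master seed and entity identifiers, so per-subject output is
  independent of cohort ordering and every run is bit-reproducible.

## Problem sizes used in validation

The validation suite scales signal lengths to what the checks need, as a
design choice documented here: filter and spectral oracles run on
20–60-second probes; slope-recovery Monte Carlo uses 100 replicates per
programmed slope on a single 30-minute work bout (3 ten-minute windows) —
the estimator is linear, so bout length affects variance, not bias, and
the tolerance adapts via the Monte-Carlo standard error; anomaly-screen
rates use 3.5-hour recordings (21 windows); statistical calibration uses
200 replicates of the full 24-worker survey/heart-rate design on a
50-minute day, with one observation per subject (the shift-end period) —
deltas at different periods share the subject's baseline rating, so
pooling periods would violate the independence the calibrated tests
assume under the null; determinism runs the complete file pipeline twice
on the compressed demo day. Full-day (7.5-h) defaults remain in place for real
use and are exercised by the longer-running examples.

## Known limitations

* The anomaly screen reconstructs a PCA-based window screen from its
  feature set (amplitude percentiles, spectral frequencies, total power);
  it is a principled implementation of that idea, not a bit-level
  reimplementation of any particular field system.
* The pooled slope model uses fixed effects; with many subjects and few
  windows a mixed model could be more efficient, but fixed effects keep
  the estimator transparent and match the adjust-then-correlate workflow
  the battery implements.
* Associations are observational; nothing here supports causal readings.
* The reserve formulas use the age-predicted maximum (220 − age) and the
  sitting-minus-10 resting approximation; both are field conventions with
  known individual-level error, which is why they are isolated in
  `compute_hrr()` and easy to replace.
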