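---
title: "From collar accelerometry to activity budgets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From collar accelerometry to activity budgets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bearbehave)
```

`bearbehave` turns 8 Hz tri-axial collar accelerometry from brown bears
into behaviour classifications and the response variables of a
hunting-risk activity analysis. This vignette is the package's account of
how each stage works, which conventions were fixed where several were
defensible, and what the synthetic-data module does and does not emulate.

## Data model

A raw stream is a time-sorted table of `timestamp`, `acc_x`, `acc_y`,
`acc_z` in gravitational units (g), with the axes oriented as sway
(side-to-side), surge (forward–backward) and heave (up–down). Nominal
sampling is 8 Hz; samples are treated as contiguous when successive
intervals are within 1% of `1/fs`. An input in m/s² can be converted with
`compute_features(units = "ms2")` (division by 9.80665); no resampling,
interpolation or axis re-orientation is performed — irregular streams
simply produce incomplete windows.

## Signal chain and the 36 features

**Windowing.** `partition_windows()` tiles consecutive, non-overlapping
3 s windows (24 samples) anchored at the first sample's clock. A window is
*complete* only when it holds the full 24 samples with no internal gap;
incomplete windows (recording gaps, trailing partials) are flagged and
dropped, never padded. Three seconds is long enough to hold a few gait
cycles and short enough to keep rare behaviours represented after
partitioning.

**Static acceleration** is a 3 s running mean per axis. The window is
centred — 12 samples before, the current sample, 11 after — and truncated
symmetrically at recording edges. A centred mean avoids the phase lag a
trailing mean would introduce between the static estimate and the raw
signal; the one-sample asymmetry is unavoidable with an even width.
`compute_features()` evaluates the mean on the continuous stream *before*
windowing, so interior window edges borrow their true neighbours; only
recording boundaries are truncated. `summarize_window()`, which sees a
window in isolation, truncates at the window edge instead.

**DBA, ODBA, magnitude.** `DBA = raw − static` per axis (the decomposition
is exact: `static + DBA` reconstructs the raw signal bit for bit);
`ODBA = |DBA_x| + |DBA_y| + |DBA_z|` per sample; magnitude is the
Euclidean norm of the raw axes.

**Feature vector.** Each complete window yields exactly 36 finite values,
in the fixed order of `feature_names()`: mean, SD, max, min, kurtosis and
skewness of each raw axis and of the magnitude (24); Pearson correlations
between raw axis pairs (3); mean DBA per axis (3); total and mean ODBA
(2); dominant power spectral density of each axis and of the magnitude
(4). Conventions fixed here:

* SD is the sample standard deviation (n−1 denominator).
* Skewness and kurtosis use population moments, `m₃/m₂^1.5` and `m₄/m₂²`
  (kurtosis is not excess-corrected; a Gaussian channel sits near 3).
* Correlations are computed on the raw axes, since axis correlation is a
  posture/gait signature that the static component carries as much as the
  dynamic one.
* Zero-variance channels — possible in resting windows with quantised
  sensors — get correlation, skewness and kurtosis 0 rather than `NaN`,
  so degenerate windows remain classifiable.
* Total and mean ODBA are proportional inside fixed-length windows
  (`odba_total = 24 × odba_mean`); both are retained because the
  established 36-feature set lists both, and the forest is indifferent to
  the redundancy.

**Dominant power spectrum.** The periodogram of the mean-removed window —
no taper, no detrending beyond the mean — one-sided over positive
frequencies, with density `2|X_k|²/(n·fs)` (Nyquist bin not doubled). The
returned feature is the maximal *density value*, not its frequency;
doubling a sinusoid's amplitude quadruples it, and a constant channel
returns 0. At 24 samples the resolution is 1/3 Hz, coarse but sufficient
to separate a 1.5 Hz walk from a 3 Hz gallop.

All features are validated in the test suite against an independent
brute-force implementation (explicit loops and DFT sums) at 10⁻⁹ relative
tolerance.

## Preparing training data from annotated video

`clean_events()` canonicalises labels (case/whitespace-insensitive), keeps
the four ethogram behaviours, drops the seven known rare behaviours
(playing, fighting, shaking, scratching, swimming, tree rubbing,
drinking), and warns about anything else. Transitions are excluded later
by construction, not by labelling.

Annotation clocks typically lead the accelerometer clock by one to three
minutes. `estimate_clock_lag()` automates the usual visual alignment: it
scans candidate lags, correlating the binary active/inactive event
indicator with per-second mean ODBA, and returns the argmax (ties to the
smallest lag; correction is `apply_clock_lag(events, -lag)`). The
objective is flat when all events are active or all inactive, which is
rejected as an error rather than returning an arbitrary lag.

`build_training_windows()` tiles 3 s windows *within* each event,
restarting the grid at every event start. Anchoring at the event rather
than a global grid means a 10 s event yields its full three windows
regardless of phase; since a window is kept only when wholly inside one
event, no emitted window can straddle a behaviour boundary. Tests verify
emitted labels against the simulated schedule at window midpoints.

## The classifier

`train_forest()` fits a seeded random forest (default 1000 trees) on the
36 features. `tune_mtry()` selects the number of predictors per split by
out-of-bag error over the candidate set {3, 6, 9, 12, 18} — a
doubling/halving neighbourhood of `floor(sqrt(36)) = 6`, the usual
classification default — with ties to the smallest candidate and the full
error table returned for logging. Other tree hyper-parameters stay at the
engine defaults (node size 1, unlimited depth) and are recorded in the
model's `config`. Determinism is mandatory: the same seed reproduces the
fit, the OOB error and the OOB confusion matrix exactly, and prediction
ties are broken by the fixed class order (feeding, resting, running,
walking) rather than at random.

Evaluation uses the one-vs-rest collapse of the 4×4 confusion matrix
(rows observed, columns predicted): precision, recall and the Matthews
correlation coefficient per class, plus the overall error (off-diagonal
fraction). MCC is the headline metric because the class balance is
extreme — resting outnumbers running by ~45:1 in captive training data —
and accuracy is dominated by the majority class. A metric whose
denominator is zero is reported `NA`, never silently 0. The OOB confusion
matrix is what the package reports for a trained model, since the OOB
error is the quantity the off-diagonal of the published matrix matches.

## Activity budgets

**Feedwalking.** In August wild bears forage on berries by walking slowly
while feeding, and window-level classifications separate the two poorly
(walking proportions collapse for many bear-years while resting and
running stay stable). Walking and feeding predictions are therefore pooled
into one *feedwalking* state; counts are conserved exactly.

**Bouts.** `detect_bouts()` run-length-encodes the window label stream: a
bout is a maximal run of consecutive target-label windows, ended by any
other label, a recording gap, or a change of animal; duration is
`n_windows × 3 s`. The bout set is tested against an independent RLE
oracle over 10⁴ random sequences.

**Legal hours.** Legal bear-hunting hours run from 1 h before local
sunrise to 2 h before local sunset. Sunrise and sunset come from the NOAA
solar-position formulae (zenith 90.833°) at the fixed study centroid
(61° N, 15° E) — per-bear GPS positions would move the bounds by under a
minute across the study area and are not used. The interval is half-open
(`[start, end)`), a bout belongs to it by its *start* timestamp (bouts are
seconds long, so start vs midpoint is immaterial, but the rule must be
fixed), and dates cut at local midnight UTC+2.

**Daily records.** One record per bear-day: running-bout count, legal-hour
bout count, their proportion (`NA` on zero-bout days — a missing
proportion is not 0), study period (Aug 1–20 pre-hunting / Aug 21–31
hunting), demographic group from a per-bear metadata table (age/sex
classification is upstream of this package), and daily GPS distance.

**GPS distance.** The sum of straight-line distances between successive
hourly fixes, each segment assigned to the local date of its *starting*
fix, so a complete day of hourly fixes contributes its 24 segments to that
day. Planar tracks use Euclidean distance; lon/lat tracks use great-circle
distance via `geosphere`.

**Subsampling and export.** Using every 3 s window in regression models
induces severe serial dependence, so `subsample_hourly()` draws 10 windows
per bear-day-hour (seeded, order-insensitive) and `export_model_table()`
emits the analysis-ready window table (bear, year, date, time-of-day in
seconds, period, group, feedwalking/resting indicators) plus the daily
records — the inputs of downstream GAMM/GLMM fits, which are out of scope
here. `diel_profile()` gives a descriptive per-hour feedwalking
probability with a percentile bootstrap over bear-days (the exchangeable
unit; windows within a day are dependent). With `n_boot ≤ 1` no resampling
spread exists and the interval degenerates to the point estimate.

## The synthetic-data module

The generator produces the statistical structure the pipeline assumes,
with ground truth attached everywhere.

* **Schedule**: a semi-Markov chain with exponential dwell times per
  behaviour. Exponential dwells are the simplest choice consistent with
  the strong overdispersion of observed running bouts (mean ≈ 9 s with SD
  larger than the mean). At each transition the next state is drawn with
  weights — resting 1, running 0.15, feeding and walking each at the diel
  profile's weight for the current hour — which yields the crepuscular,
  bimodal activity pattern of late-summer bears.
* **Diel profile**: 24 hourly weights, default Gaussian bumps at 05:00 and
  20:00 over a 0.05 floor. The peaks are deliberately narrow (width 1 h)
  and the floor low: transition probabilities saturate quickly, and a
  flatter profile would leave the simulated activity maximum statistically
  indistinguishable between adjacent hours.
* **Acceleration**: per behaviour, a static gravity vector plus — for
  gaited behaviours — a single sinusoid on surge with the same sinusoid
  90° out of phase on heave, plus white Gaussian noise per axis. Defaults:
  resting noise 0.02 g; feeding 0.08 g; walking 1.5 Hz gait at 0.25 g;
  running 3 Hz at 0.8 g. These are *fixtures*, chosen so that mean window
  ODBA orders running > walking > feeding > resting; no per-behaviour
  acceleration magnitudes for wild bears exist to calibrate against, and
  none are claimed. Gait frequencies at or above Nyquist (`fs/2`) are
  rejected.
* **Annotations**: schedule entries shifted by a configurable clock lag
  (the annotation clock leads) with Bernoulli event dropout.
* **GPS**: one planar fix per hour whose step length is the interval's
  active-time fraction times a nominal 500 m per fully active hour, with
  uniform headings.

All generators take explicit integer seeds and are exactly reproducible.

What the generator does **not** emulate: gait harmonics and inter-stride
variability, posture transitions inside a behaviour, autocorrelated sensor
noise, collar rotation, temperature drift, or habitat-driven movement.
Consequently the near-perfect classifier performance on synthetic data
demonstrates that the chain — features, training, tuning, prediction,
evaluation — is implemented correctly and recovers a known signal; it says
nothing about field accuracy, which is established by the captive-bear
confusion matrix the evaluation code reproduces.

## Problem sizes and numerical choices in the checks

The test suite runs the feature oracle on 100 random windows (10⁻⁹
relative tolerance), the bout oracle on 10⁴ random sequences, classifier
label-recovery at 500 windows per class over five seeds (per-class recall
≥ 0.90 on held-out data), and a 31-day, multi-bear population simulation
for the legal-hour direction check — sizes chosen to exercise every code
path at comfortable statistical power while keeping a full run around a
minute. Floating-point comparisons use the brute-force oracles' exact
conventions; scheduling uses a 10⁻⁹ s tolerance when assigning samples to
grid slots so that representable 1/8 s timestamps never land on the wrong
side of a window boundary.

## Known limitations

* The classifier is only as transferable as its training data; captive
  bears differ from wild bears in gait context and collar fit, which is
  precisely why feedwalking pooling exists downstream.
* Legal hours use one fixed site; studies spanning degrees of longitude
  should generalise `study_calendar()` per animal.
* The GAMM/GLMM stage of a hunting-risk analysis is out of scope: this
  package produces its inputs (`export_model_table()`), not its
  coefficients.
* `estimate_clock_lag()` assumes the lag is constant over the session; a
  drifting clock would need piecewise estimation.
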