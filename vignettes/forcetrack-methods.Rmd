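---
title: "Force-profile analytics for surgical performance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Force-profile analytics for surgical performance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forcetrack)
```

## The problem

Bipolar forceps instrumented with force sensors record the tool–tissue
interaction force of both prongs continuously during surgery. Annotated
episodes of force application — *segments* — carry a task label (one of
Retracting, Manipulation, Dissecting, Pulling, Coagulation), the operating
surgeon and a binary experience level (Expert vs Novice). From these
segments the package derives objective performance measures: engineered
time-series features, statistical screening of those features, an
expert-vs-novice classifier, a task recogniser, and per-surgeon gauge
metrics benchmarked against the expert.

The package operates on plain CSV/JSON files and deliberately contains no
acquisition, voice-annotation or dashboard-rendering code: annotations are
consumed as files, and gauge panels are emitted as JSON for any front end.

## Data model and segmentation

A `force_recording` holds two force channels on a strictly increasing time
base; its sampling rate is inferred from the median time step unless
supplied. Segmentation assigns sample *i* to an annotation iff
`start + offset <= t[i] < end + offset`. The half-open convention
prevents double assignment when annotations share boundaries, so
annotations that tile a recording partition its samples exactly. The
scalar `clock_offset` absorbs any constant clock difference between the
annotation track and the force logger; estimating that offset (e.g. from
synchronization beeps) is out of scope. Device sampling rates vary between
installations, so the rate is always explicit in the objects and never
assumed.

## Preprocessing

**Smoothing.** Segments are low-pass filtered with a digital 4th-order
Butterworth filter (default cutoff 0.1 Hz, interpreted as absolute Hertz).
The default mode is zero phase: the filter runs forward and backward, so
the magnitude response is squared (gain 1/2 at the cutoff, twice the
stopband attenuation in dB) and no phase lag biases duration-aligned
features. A causal single-pass mode is retained for streaming parity.
Because the normalized cutoff can be very small (0.1 Hz at a 100 Hz
sampling rate), start-up transients would dwarf typical segment lengths;
the implementation therefore uses steady-state initial conditions plus
odd-reflection padding of `3 * (2 * order + 1)` samples per side, which
makes constants pass through exactly and defines the minimum filterable
segment length (28 samples at order 4). Both cutoff and sampling rate are
configuration, never hard-coded, since plausible force dynamics depend on
the installation.

**Outlier removal.** Experienced surgeons are assumed to err in fewer than
1% of segments, so the 1st and 99th percentiles of three per-segment
statistics — maximum force, minimum force and completion time — over all
Expert segments define acceptance bands. A segment is an outlier iff *any*
statistic leaves its band; with three criteria and two 1% tails the
flagged fraction of expert-like data is at most ~6% before overlap.
Percentiles use the linear-interpolation definition (R type 7). Flagging
and removal are separate pure functions so every decision is auditable,
and smoothing precedes thresholding. The statistics are taken on a single
designated analysis channel (right prong by default, configurable to left
or the elementwise maximum). Thresholds depend only on Expert segments;
the realized removal rate on clinical data is data-dependent and is not a
contract of the method.

## The 37-feature engine

Each segment is summarized by a fixed, ordered catalogue of 37 features
computed on the analysis channel. Groups and the principal conventions:

* **Moments** — duration; mean, max, min, range, median, sample SD,
  CV (`sd/mean`, undefined at zero mean) and the 95% CI half-width
  `t(0.975, n-1) * sd / sqrt(n)`.
* **Distribution shape** — adjusted sample skewness and excess kurtosis,
  each also divided by twice its closed-form standard error (significant
  when the ratio exceeds 1 in magnitude), and the Shapiro–Wilk statistic
  and p-value (defined for 3 ≤ n ≤ 5000).
* **Peaks** — local maxima with topographic prominence of at least 5% of
  the segment range (the prominence rule is a package convention,
  configurable); peak value, peak count, mean inter-peak interval
  ("cycle length", undefined below two peaks) and the SD of the first
  derivative.
* **Flat spots** — the longest run of consecutive samples within one of
  ten equal-width force bins; a constant segment returns its length.
* **Spectrum** — dominant frequency of the raw FFT periodogram after mean
  removal, and spectral entropy: the Shannon entropy of the normalized
  periodogram divided by `log` of the ordinate count, in [0, 1]. Low
  entropy means a concentrated spectrum, i.e. a forecastable,
  high signal-to-noise profile.
* **Trend decomposition** — a loess fit (span 0.75, degree 2) on the time
  index estimates the smooth trend; `trend = max(0, 1 - var(rem)/var(x))`;
  spikiness is the variance of leave-one-out variances of the remainder
  (computed by a streaming O(n) identity, validated against the literal
  double loop); curvature is the quadratic coefficient of an orthogonal
  polynomial regression; linearity is a Teräsvirta-style neural-network
  nonlinearity statistic (one lag, chi-squared form, on the standardized
  series). The "fluctuation" index has no canonical formula in the
  dashboard literature; here it is the mean-crossing count divided by
  n−1, which is bounded in [0, 1] and scale-invariant. This
  interpretation is explicit and isolated so it can be swapped.
* **Windowed shifts** — non-overlapping 10-sample windows give stability
  (variance of window means) and lumpiness (variance of window
  variances); a sliding pair of adjacent windows gives the largest
  absolute mean difference, variance difference and Gaussian
  Kullback–Leibler divergence (first window relative to the second,
  variances floored at 1e-8). The window width is a convention exposed in
  `feature_config()`.
* **Stationarity** — the KPSS statistic with linear detrending and lag-1
  Bartlett long-run variance; 0.119 and 0.216 are the 10% and 1% critical
  values of this variant.
* **Autocorrelation** — lag-1 coefficient, sum of the first ten squared
  coefficients, time of the first local ACF minimum and the first zero
  crossing (linear interpolation between lags, starting from ACF(0)=1).

Any unmet precondition (short segments, zero variance) degrades the
affected entries to `NA`; the catalogue is always complete, in fixed
order, and extraction is deterministic. Downstream consumers either use
complete cases per feature (screening) or impute training-split medians
(models). Features are computed on the smoothed signal, after outlier
removal, matching the pipeline ordering.

## Feature screening

Each feature is tested with an independent-measures two-way ANOVA
(experience × task, with interaction) on complete cases. Type II sums of
squares are used because realistic segment tables are heavily unbalanced
across cells (hundreds of Coagulation segments versus a few dozen
Dissecting ones); on balanced designs Type II reduces to the classical
decomposition, which the tests verify against explicit residual-sum-of-
squares differences. Post-hoc task contrasts are Tukey-HSD-adjusted
pairwise mean differences. P-values are reported per feature without
multiple-testing correction by default (a Benjamini–Hochberg switch
exists). Segments are treated as independent observations even though
they are repeated measures within surgeons — a deliberate simplification
of the screening stage, noted as a statistical caveat.

Model building uses a fixed 25-feature subset obtained by removing 12
features found uninformative in the reference screening of the clinical
corpus this pipeline was designed around (`FIXED_EXCLUDED_FEATURES`); a
threshold mode retains any feature with a main-effect p-value below a
chosen alpha instead.

## Skill classification

`train_skill_model()` is a leak-free pipeline: a seeded stratified 70/30
train/test split; median imputation, standardization and PCA (components
retained to 95% of training variance) fitted on the training split only;
then an RBF-kernel SVM grid-searched over cost × gamma by 5-fold
cross-validated training accuracy. The grids include `0.1 * 10^0.1`
(≈ 0.1259), the optimum reported for the reference clinical experiments.
Sensitivity is the recall of the Expert class, specificity of the Novice
class, and AUC comes from decision scores on the test split with a fixed
orientation (larger = more Expert-like), so chance-level data yields
chance-level AUC rather than being flipped to 0.5+. Split fraction, fold
count, PCA rule and class weighting are all configuration with recorded
defaults, since the reference experiments do not state them.

## Task recognition

Segments of variable length enter the network as fixed-length vectors:
linear interpolation onto `input_length` (default 100) equally spaced
points followed by per-vector standardization; a zero-variance segment
maps to the zero vector. The resampling rule is isolated in
`resample_segment()` so padding/truncation alternatives can be swapped.

The network is exactly input → LSTM(100) → dropout(0.5) → dense(100,
ReLU) → softmax(5), trained with Adam on categorical cross-entropy
(batch size 20). It is implemented directly in C++ (RcppArmadillo) with
its own Mersenne-Twister RNG, so training is single-threaded and
bit-reproducible for a given seed. Training runs `n_repeats` times
(default 4) with derived seeds; reported metrics are the mean (SD) over
repeats of the held-out cross-entropy loss, accuracy and the mean squared
error between one-hot labels and softmax outputs (MSE is a monitoring
metric, not the loss). All reported metrics are held-out values, and are
labelled as such. The tested desk-scale profile is 200 epochs on up to
~1000 segments, which the synthetic corpus saturates; the 1000-epoch
configuration of the reference experiments is reachable via `epochs`.

## Performance gauges

Four representative measures summarize performance on the dashboard:
completion time (`duration`), force range (`range`), the variability
index (`fluctuation`) and the uncertainty index (`spectral_entropy`).
`compute_baseline()` takes their mean and sample SD over all Expert
segments; `gauge_panel()` aggregates a surgeon's segments over a selected
case range by unweighted mean (per-case weighting is a config switch) and
reports z-scores against the baseline. Z-scores let any front end draw
whatever band convention it prefers (mean ± 1 SD, ranges, …).

## The synthetic generator

`generate_segments()` stands in for clinical recordings, which cannot be
distributed. Its default profile reproduces the reference corpus's
printed summary statistics: per-task completion-time and force-range
means/SDs, and per-cell segment counts (1645 Expert + 1250 Novice
segments, 2085 of them Coagulation). Durations and ranges are drawn from
log-normal distributions moment-matched to those targets (`mu = log(m) -
s2/2`, `s2 = log(1 + (s/m)^2)`), since both quantities are positive and
right-skewed; durations are floored at 0.25 s so every segment supports
the feature preconditions. Each task has a distinct amplitude motif —
sustained plateau (Coagulation), monotone ramp with release (Pulling),
oscillation (Manipulation), burst train (Dissecting), grasp-and-hold
(Retracting) — scaled to the drawn range on a 0.2 N baseline, plus
Gaussian noise. The experience contrast enters through the noise SD
(0.04 N Expert vs 0.10 N Novice, raising within-segment SD, mean-crossing
rate and entropy for novices) and a novice peak multiplier of 0.39/0.35
on the motif amplitude. The default sampling rate is 100 Hz, which turns
the typical printed durations into segments of roughly 500–1200 samples —
comfortable for every feature precondition.

What the generator does *not* emulate: tissue mechanics, inter-surgeon
learning curves, correlated left/right prong asymmetries beyond a fixed
attenuation, event flags (bleeding, repeat-task), or heavy-tailed sensor
artefacts. Passing tests on synthetic data therefore demonstrate the
*correctness and sensitivity of the pipeline*, not clinical
performance; the reference clinical metrics (skill AUC 0.65, task
accuracy 0.83) live in a regime of overlap and noise the generator does
not attempt to copy, and the package makes no claim to reproduce them.

## Numerical conventions and degenerate inputs

* Percentiles: linear interpolation (R `type = 7`) throughout.
* `NA` is the universal not-available sentinel; it propagates, is never
  silently dropped, and is written as an empty CSV cell.
* Variances inside the KL shift are floored at 1e-8; the KL direction is
  first-window-relative-to-second.
* Zero-variance series: Shapiro, spectral, ACF and KPSS entries are `NA`;
  flat spots return the segment length; resampled model inputs become
  zero vectors.
* Peak definition is strict (`x[i]` above both neighbours); exact-tie
  plateaus are not peaks. Ties at bin edges in flat spots go to the lower
  bin (`findInterval` with closed right edge).
* Seeded operations (generator, model fits) save and restore the global
  RNG state, so library calls do not disturb the caller's random stream.
* The grid-search tie-break is "first best" in (cost, gamma) row order,
  which is deterministic.

## Scale of the shipped test evidence

The test-suite and acceptance-script problem sizes are chosen as the
smallest that make each check statistically meaningful: oracle
equivalence on 50+ random series per statistic, filter response on
12 000-sample sinusoids, the outlier rule exhaustively on 1000 expert
segments, skill-model recovery on 200 segments/class clouds with 20
permutation replicates, the task recogniser on 500 segments at 200
epochs, and the ANOVA screen's power/specificity over 50–100 seeded
replicates. These sizes are package choices and can all be scaled up via
the same functions.

## Known limitations

* The ANOVA ignores within-surgeon correlation (by design of the
  screening stage); a mixed-model screen would be the principled upgrade.
* The Teräsvirta and fluctuation features are stated interpretations of
  loosely specified dashboard quantities; both are isolated and
  configurable.
* The LSTM is CPU-oriented; very large corpora would need minibatch
  streaming or a GPU backend, neither of which this package targets.
* With a single expert surgeon as baseline, gauge z-scores conflate
  "different from this expert" with "worse"; multi-expert baselines are
  future work.
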