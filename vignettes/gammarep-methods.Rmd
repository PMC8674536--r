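---
title: "Measuring stimulus-specific repetition effects in V1: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring stimulus-specific repetition effects in V1: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gammarep)
```

# The scientific problem

When a visual stimulus is repeated, primary visual cortex changes its
response: firing rates typically decrease (repetition suppression), while
narrowband gamma oscillations (~30-90 Hz) in the local field potential
(LFP) often grow stronger and shift in peak frequency. The central
question this package addresses is whether those repetition trajectories
are *stimulus-specific* — does the cortex track each image's repetition
history separately, even when repetitions are interleaved with other
images and separated by minutes? — and whether the induced state
*persists* across blocks of intervening stimulation.

Answering this requires a statistic that detects consistent per-stimulus
trajectory shapes across recording sessions without being fooled by
trends shared across all stimuli, plus careful resampling inference.
`gammarep` implements the full pipeline and a synthetic-data generator so
that every inferential claim can be validated against planted ground
truth.

# The synthetic-data generator

## Task designs

Three trial-sequence designs are generated:

* **Constrained-lag natural-image sequences**
  (`generate_natural_sequence()`): 25 stimuli repeated 20 times each (one
  block of 500 trials). On each trial a stimulus is drawn from a rolling
  subset of 3; a stimulus whose pending lag (intervening other-stimulus
  trials) has reached the cap of 4 is presented immediately, and
  exhausted stimuli are replaced by unused ones. This interleaves
  repetitions while bounding the lag, and spreads each stimulus's
  presentations over a different part of the session on different days.
  An optional prefix interleaves two "dummy" stimuli with the first
  stimulus so set stimuli enter the sequence staggered rather than
  simultaneously.
* **Grating blocks** (`generate_block_sequence("ABA", 100)`): three
  blocks of 100 direct repetitions, with the middle block either a
  different grating (ABA) or the same one (BBA). Blocks are labelled in
  bracket notation — `A[B]A` is the middle block of ABA — and the mapping
  of physical gratings to the roles A/B is counterbalanced across
  sessions.
* **Location blocks** (`generate_block_sequence("InOutIn", 50)`): the
  same grating presented either on the recorded receptive fields ("In")
  or at an equi-eccentric control location ("Out"), switching every 50
  trials.

Trial correctness is an independent Bernoulli draw with a higher error
rate on the first three presentations of a stimulus (new stimuli provoke
more fixation breaks); the repetition number counts correct trials only.
The interval from stimulus onset to the behaviorally relevant change is
drawn from a standard Weibull distribution (scale 0.27, shape 2 by
default), whose shape-2 hazard grows linearly within the trial. We
deliberately expose scale and shape directly: the parameterization of
reported change-time distributions in this literature is not always
internally consistent, and the standard form with an explicit hazard is
the unambiguous choice.

## Signals

`synthesize_recording()` emits site x trial x time arrays at 500 Hz over
a -1.3 to +1.5 s peri-stimulus window (onset at 0):

* **LFP** = 1/f^1.5 background noise plus, during stimulation, a
  narrowband gamma oscillation implemented as a Brownian-phase oscillator
  (default ~6 Hz linewidth) with a 50 ms onset ramp. The oscillation
  amplitude is calibrated against the analytic background density so that
  `gamma_base_power` equals the excess gamma-band power within +-16 Hz of
  the peak, in units of the background power there — making the
  stimulation/baseline band ratio approximately `1 + gamma_base_power`.
* **MUA envelope** = per-site noise floor plus an onset transient and a
  sustained rate, non-negative by construction, and multiplicatively
  modulated by the LFP gamma phase with configurable depth (this is what
  gives MUA-LFP phase locking a known positive target).
* **Repetition trajectories**: each stimulus has its own early
  (repetitions 1-4) and late (5+) slopes for gamma power and MUA rate;
  block designs use log-linear trajectories in trial-in-block. The
  `specificity_transfer` parameter in `[0, 1]` mixes each stimulus's
  trajectory with the stimulus-average trajectory: 0 plants fully
  stimulus-specific effects, 1 fully shared ones. `persistence` carries a
  fraction of the accumulated repetition state across an intervening
  block by continuing the effective trial count.

Default effect sizes emulate the qualitative physiology: gamma band power
a few-fold above background (`gamma_base_power = 3`), early gamma slopes
variable across stimuli with a negative mean (mean -0.04/repetition, SD
0.06), a weakly positive late gamma slope, and MUA decaying by ~12% over
the first four repetitions (-0.04/repetition early, -0.006 late). Peak
frequencies are drawn uniformly in 35-75 Hz and drift upward by
2 Hz per decade of repetitions.

`synthesize_band_responses()` is the feature-level counterpart: it emits
the per-trial gamma-band ratio and sustained dMUA rate the signal model
induces, with log-normal measurement noise. Calibration and power
studies use it because decomposing thousands of full LFP sessions adds
cost but no information about the statistics under test; the
signal-to-feature equivalence is itself covered by round-trip tests.

What the generator does **not** emulate: raw broadband signals, spike
sorting, realistic retinotopy or receptive-field structure, eye-movement
artifacts in the LFP, correlated noise across sites beyond the shared
gamma phase, non-Poisson spiking statistics. Passing tests therefore
demonstrate correctness of the *analysis* under the stated statistical
structure, not fidelity of the generator to any particular recording rig.

# Preprocessing

* **dMUA** (`compute_dmua()`): MUA is averaged in 10 ms bins over -1 to
  1.5 s, and the per-site minimum over all bins and trials is subtracted
  — the minimal observable activity is the best available estimate of a
  site's noise floor, so the output minimum is exactly 0 per site. The
  minimum is taken over binned means (not raw samples) and only within
  the analysis span.
* **Smoothing** (`smooth_rate()`): Gaussian kernel, SD 20 ms, reflection
  padding. Latency-sensitive analyses must use unsmoothed input.
* **Baseline normalization** (`baseline_normalize()`): trial-wise
  responses divided by a session-average per-site baseline (-0.95 to 0 s
  for rates; the trial-averaged -1 to 0 s spectrum for power). The
  baseline is never computed per trial; the ratio is invariant to
  per-site gain.
* **Epoching** (`epoch_signal()`): non-overlapping, left-aligned epochs
  with half-open sample bins; `floor(window / epoch_len)` epochs per
  trial; concatenation reproduces the original samples exactly.
* **Re-referencing** (`derive_sites()`): common-average or bipolar
  (time-domain differences of neighboring sites, each unipolar channel
  used at most once).

# Spectral estimation

Two configurations (`taper_cfg()`): 500 ms Hann epochs (2 Hz grid) for
grating responses and low frequencies, and 250 ms epochs with DPSS
multitapers for gamma-band analyses. The taper count follows `K = 2TW`:
250 ms epochs with +-10 Hz smoothing give exactly 5 tapers. The
alternative reading `K = 2TW - 1` is exposed as an option but not the
default, because the 5-taper configuration is the operative convention
throughout. DPSS tapers are computed from the standard symmetric
tridiagonal eigenproblem, unit-energy, and are verified in the test suite
against an independent reference implementation. No zero padding is
used, so the frequency grid is 4 Hz (250 ms) or 2 Hz (500 ms). Power is
scaled as one-sided spectral density so that its integral tracks signal
variance (checked to within 5% on white noise).

MUA-LFP locking uses per-epoch cross-spectra normalized to unit
magnitude (phase-only), pooled over stimulus-window epochs, and the
**pairwise phase consistency**

$$\mathrm{PPC} = \frac{2}{N(N-1)} \sum_{j<k} \cos(\theta_j - \theta_k)
= \frac{|\sum_j z_j|^2 - N}{N(N-1)},$$

which is unbiased by the number of observations (the closed form is
required to agree with the brute-force pairwise sum to 1e-12). Only
direct array-neighbor MUA-LFP pairs enter, same-electrode pairs are
excluded to avoid spike-bleed artifacts, and the PPC is averaged over a
site's neighboring LFPs.

A note on an estimator property the tests document: for a pure tone
sitting exactly on a frequency bin, antisymmetric DPSS tapers pass only
the negative-frequency image of the tone, so their cross-spectral phase
at that bin is conjugated. Phase-delay oracles in the tests therefore
use the symmetric Hann taper.

# Gamma-peak detection, validation, grouping

Per stimulus, strict local maxima of the relative power spectrum between
20 and 190 Hz are ranked by height (ties toward the lower frequency) and
the top two kept. A candidate peak is validated by a one-sided
permutation test (1000 permutations) of the mean relative power in
peak +- 8 Hz against 190 +- 8 Hz, re-assigning the two band labels within
each trial; testing against high-frequency activity rather than baseline
guards against spike-bleed plateaus masquerading as oscillations. Band
means use bins fully inside the band (the 4 Hz grid makes +-8 and +-16 Hz
bands symmetric). Sites are grouped when their largest peaks agree
within +-16 Hz; spectra are aligned to each stimulus's peak by exact
integer-bin shifts; the gamma-band scalar is the mean over peak +- 16 Hz
(natural images) or +- 8 Hz (gratings). A stimulus enters gamma analyses
only with a validated peak on at least 5 sites, and a sequence only with
at least 8 correct trials (4 for early fits).

Because the *largest* local maximum is selected before validation, the
validation p value is a threshold, not an inference: on pure-noise
spectra the selected peak is biased upward and can validate more often
than the nominal level. The tests therefore calibrate validation at a
fixed candidate band and characterize the no-gamma case by the flatness
of the relative spectrum.

# Repetition metrics

Trajectories are z-scored across available repetitions using the
population (N-denominator) SD — the repetitions of one stimulus in one
session are the entire population of that trajectory. OLS slopes are fit
separately to early (1-4) and late (5-15) repetitions; block designs fit
`r(t) = a + b log10(t)` over trials 5+ in each block. From the fitted
endpoints, the repetition-related change is

$$\mathrm{RRC} = \frac{r_\mathrm{last}}{\tfrac12 (r_\mathrm{last} +
r_\mathrm{first})},$$

equal to 1 under no change and robust when responses approach zero
(where the naive ratio degenerates; denominators below 1e-6 are excluded
and counted).

**Drive dependence** asks whether strongly driven stimulus-site
combinations adapt more. A naive correlation of fitted slopes with
fitted intercepts is biased because both come from the same fit; the
package fits two interleaved halves of the repetitions (odd-indexed and
even-indexed), medians slopes and intercepts across sessions, and
Spearman-correlates the slope of each half with the intercept of the
*other*, averaging the two directions. The test suite demonstrates the
bias of the naive estimator and the removal by cross-validation. A
median split by intercept (lower half taking the extra point) with a
permutation test per half (randomizing intercepts within animal,
averaging across animals, Benjamini-Hochberg across the two halves)
controls for floor effects in weakly driven combinations.

# The split-half specificity statistic

Per session, site and stimulus, the repetition trajectory of the feature
of interest (gamma-band power, PPC, or dMUA per time bin) is z-scored,
averaged across sites, and concatenated across stimuli in a fixed
lexicographic order into one session vector; sessions with under 50%
vector coverage are excluded. For `s = 100` random equal-size session
splits, the two half-average vectors are Pearson-correlated
(pairwise-complete) and the mean over splits is the observed statistic;
with several animals, values are averaged across animals.

The null asks whether this correlation requires matched stimulus
identity. Each of 1000 permutation iterations draws **one** random
stimulus order and applies it to the half-2 average of *every* split,
correlating against the intact half-1 average; the s values are averaged
exactly as for the observed data, and observed-vs-null comparison is
two-sided at alpha 0.05, with Benjamini-Hochberg FDR across frequency or
time bins.

Two design points deserve emphasis:

* **One stimulus order per iteration, shared across splits.** Drawing an
  independent order per split would average ~s nearly independent
  correlations per null draw, shrinking the null variance roughly
  s-fold; on exchangeable noise that variant rejected 66% of the time at
  alpha 0.05 in our simulations. With the shared order, the observed
  statistic is the identity member of each iteration's orbit and the
  measured level on exchangeable data is ~5%.
* **The permutation orbit is discrete.** With k stimuli there are k!
  orders; below 5 stimuli a two-sided test cannot reach p < 0.05 at all.
  The intended operating range (25 stimuli) is far from this limit, but
  small simulations must respect it.

A documented limitation: when per-stimulus trajectories carry iid random
shape jitter on top of a strong shared trajectory — for example, when
trial errors randomize the mapping from repetition number to the
underlying adaptation state — the one-half block-permutation null does
not capture that jitter and the test becomes anti-conservative (we
measured 15-30% rejection in such regimes). Calibration claims are
therefore made, and tested, for complete error-free trajectories; with
substantial missingness or shape jitter the statistic remains a useful
effect measure but its p values should be treated cautiously.

# Inference machinery

* **Sign-flip test**: per-session values, null from random sign flips of
  each session, 1000 permutations.
* **Exchange test**: paired condition values per session, null from
  independent per-session swaps.
* **Two-sided p convention**: double the smaller tail count, floored at
  one permutation — `p = min(1, 2 max(1, min(#{null >= obs},
  #{null <= obs})) / n_perm)` — so the minimum attainable p with 1000
  permutations is 0.002 and the empirical type-I error is ~5% at alpha
  0.05 (both properties are asserted in the acceptance tests; the naive
  `2 #{|null| >= |obs|} / n_perm` convention halves the type-I error and
  was rejected for that reason).
* **Bootstrap SEM**: sessions resampled with replacement 1000 times
  within animal-stimulus cells, averaged across sessions, stimuli, then
  animals; the SD of the resampled grand means is the SEM and plots show
  +-2 SEM.
* **FDR**: Benjamini-Hochberg step-up at rate 0.05 across bins.
* **Block regression** (`fit_block_regression()`): OLS on
  log10-transformed site-averaged responses (so strong stimuli do not
  dominate) with a log10 repetition term, categorical session terms,
  immediate/delayed repetition-block indicators (intercept shifts =
  persistence/specificity) and their interactions with the repetition
  term (slope changes). Location designs model only In-location trials
  of the contrast blocks, with a local (location-specific) log repetition
  count against the overall trial count. Rank-deficient terms are
  reported as aliased; per-term variance is the drop-one sum of squares
  over the total.
* **Behavior**: microsaccades are detected on +-5 ms boxcar-smoothed gaze
  velocities (differences across ~10 ms) with a per-trial, per-axis
  threshold of 6c, where `c = sqrt(median(v^2) - median(v)^2)` is a
  median-based robust velocity SD; threshold crossings on either axis
  merge into events when closer than 10 ms. The square root is required
  for c to carry velocity units; c scales linearly with velocity scale.
  Pupil traces are z-scored against each trial's own -1 to 0 s baseline.
* **Dataset-3 binning**: responses are averaged in centered +-3-trial
  bins within each block before block contrasts.

# Orchestration and reproducibility

`run_dataset1_analysis()` and `run_block_analysis()` chain the stages
end-to-end from a `dataset1_config()` / `block_config()` and are
bit-deterministic under the config seed; every stochastic routine takes
an explicit seed and restores the caller's RNG state. Reports carry the
exclusion ledger (sessions under coverage, stimuli without validated
peaks, degenerate RRC cases). Trial tables serialize to CSV, recordings
to a plain-text directory container (manifest with dims/rate/seed plus
array datasets), and configurations to JSON. The package's interface is
R functions; the two runner functions plus `scripts/acceptance.R` are
the batch entry points.

# Problem sizes used in the shipped tests

The statistical guarantees are exercised at sizes chosen to make the
Monte-Carlo assertions sharp while keeping the default suite fast:
calibration suites use 500 null simulations (400-1000 permutations
each); the specificity power/level study uses 100 runs of 10 sessions x
25 stimuli x 3 sites at the full s = 100, 1000-permutation setting;
parameter recovery uses 50 sessions; full-signal round trips use 2-4
sites and a handful of trials, which is ample at the synthesized SNR.
The full suite runs in about two minutes on one CPU.

# Known limitations

* The generator's gamma is a single narrowband oscillator per trial
  shared across sites; multi-peak spectra arise across stimuli, not
  within a single stimulus-site spectrum.
* Baseline normalization against a declining 1/f background pulls the
  relative-power peak up to one 4 Hz bin above the injected oscillator
  frequency; peak-recovery assertions are stated at one-bin resolution.
* Peak validation after argmax selection is a screening threshold, not
  calibrated inference (see above).
* The split-half permutation test assumes trajectory vectors without
  stimulus-level shape jitter; see the specificity section.
* Mixed-effects variants of the block regression and cluster-based
  multiple-comparison corrections are out of scope.
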