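---
title: "Methods: beta-burst quantification and WPLI² connectivity in task LFP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beta-burst quantification and WPLI² connectivity in task LFP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfpbeta)
```

## The problem

During odor discrimination learning, rodent olfactory and striatal circuits
express transient beta-band (17–28 Hz) oscillations that end near the end
of odor sampling and whose amplitude tracks learning. Quantifying them
across multi-site LFP recordings requires five coupled stages: a
time-frequency decomposition, rejection of movement artifacts, a per-trial
burst amplitude measure robust to electrode-dependent scale, a
phase-coupling measure robust to volume conduction, and behavioral labeling
of sessions relative to the learning criterion. `lfpbeta` implements all
five plus a synthetic generator that makes each stage testable against
ground truth.

## Wavelet convention

The Morlet transform is parameterized by a single dimensionless `sigma`.
We treat it as the center "frequency" of the mother wavelet
$\psi(t) \propto e^{i\sigma t}e^{-t^2/2}$: at analysis frequency $f$ the
envelope SD is $\sigma_t = \sigma/(2\pi f)$ seconds and the spectral SD is
$\sigma_f = f/\sigma$ Hz, so the *relative* bandwidth is $1/\sigma$ at
every frequency. With the analysis value $\sigma = 5\pi \approx 15.7$ this
gives $\sigma_f \approx 1.4$ Hz at 22 Hz — sharp enough to separate tones
7 Hz apart (verified empirically in the test suite) — and
$\sigma_t \approx 114$ ms, i.e. about
$\sigma/(2\pi) \approx 2.5$ carrier cycles per envelope SD. The artifact
band uses $\sigma = 3\pi$: broader in frequency, sharper in time, which is
what transient detection wants. This convention (larger `sigma` = sharper
frequency resolution) is the standard one in the wavelet literature; the
original analysis code is not public, so cross-implementation equivalence
cannot be verified — all downstream defaults and tests are self-consistent
under this convention, which we document rather than hide.

Normalization is a *unit amplitude response*: the spectral-domain window is
scaled so a unit sinusoid at a grid frequency yields coefficients of
modulus 1 (flat across the grid to < 1%). This makes the beta measure a
pure ratio, invariant to electrode gain. Coefficients are computed by FFT
multiplication; the signal is zero-padded past the widest kernel support
(6 envelope SDs at the lowest frequency) before rounding up to a power of
two, so circular wrap-around cannot reach the signal — a subtle failure
mode that the direct time-domain convolution oracle in the test suite
caught. Coefficients within 3 envelope SDs of an edge are edge-affected
(the map records this margin); baseline windows are long enough that this
is negligible in practice.

## Resampling

Signals are analyzed at 200 Hz. Resampling uses a Blackman-windowed sinc
FIR low-pass (cutoff 45% of the target rate, transition 5%, ~74 dB
stopband) convolved at a 2-3-5-smooth FFT length, then decimation on the
integer grid, or linear interpolation of the band-limited signal for
non-integer ratios. Edges are replicate-padded, so DC survives exactly. We
originally used pure Fourier resampling; R's mixed-radix FFT degrades to
O(n·p) when the signal length contains a large prime factor p, which
arbitrary session durations regularly produce, so the FIR path is both the
robust and (in this environment) the faster choice.

## Artifact detection

Per channel, at the *native* sampling rate (never below 500 Hz): mean
wavelet power over 20 linearly spaced frequencies spanning 90–250 Hz,
thresholded at `median + 25·MAD` of its own time course, where MAD is the
raw median absolute deviation without the Gaussian consistency factor
(`25·MAD` reads as the plain statistic; with the 1.4826 factor the
threshold would be ~37 raw MADs, changing sensitivity). Epochs are maximal
super-threshold runs, stored as half-open `[start, end)` intervals in
seconds. The multiplier is extreme by design: on simulated stationary 1/f
noise the false-positive time fraction is far below 1%, while 20×-RMS
transients of 20–200 ms are detected with ≥ 95% sensitivity (both are
acceptance criteria). Degenerate input (constant signal) gives MAD = 0 and
threshold = median, and since epochs require power strictly *above*
threshold, an all-zero signal yields no artifacts.

Trial exclusion windows: beta analysis drops a trial when any channel has
an epoch intersecting the 2.5 s window starting 1 s before nose-poke
start. Connectivity drops a trial when an epoch intersects a 2 s window
*around* nose-poke start or end; we read "around" as centered (±1 s),
configurable via `half_width` since the original convention is not stated.
All intersections are half-open, so an epoch ending exactly at a window
boundary does not exclude.

## Beta amplitude

Raw amplitude of a trial is the time-average, over
`[nose-poke end − 400 ms, +100 ms]`, of the per-time-point maximum
amplitude across the 17–28 Hz grid (ties break toward the lower frequency,
for determinism). The baseline is the median of the same measure over
non-overlapping 500 ms periods tiling a 240 s window centered on nose-poke
start — clipped to the recording for trials near session edges — after
dropping periods that touch any *other* trial's nose poke or any lick
interval (each extended ±200 ms) or any artifact epoch (extended ±2 s).
The own trial's nose poke is not excluded: it is the measurement target at
the window center, and excluding it would bias the baseline of
high-amplitude trials. Period tiling anchors at the window's left edge and
drops the partial trailing period. The reported **beta amplitude** is
`log(raw / baseline)` (natural log; the base only rescales). If no period
survives, the trial is flagged undefined and excluded downstream rather
than imputed.

Two properties anchor this design and are enforced as acceptance criteria:
on stationary no-burst simulations the pooled mean beta amplitude is within
±0.05 of 0 (the measure self-normalizes), and across injected gains
{1, 1.5, 2, 3} the medians increase strictly with Spearman
gain–measure correlation > 0.8.

The per-trial **time of maximal beta** (the alignment event for
connectivity) is found on the across-structure average of amplitude maps,
each first divided by the raw MAD of its own (downsampled) signal so no
electrode dominates; hippocampus and cerebellum are excluded by default
because they do not express the task beta. The search window is
`[max(end − 400 ms, trial start), end + 100 ms]`.

Blocks of 20 trials (10 per odor) are formed greedily: the n-th
presentation of an odor joins block `ceiling(n/10)`, which keeps blocks as
contiguous as the pseudo-random odor order permits; incomplete final
blocks are dropped.

## Debiased WPLI² and the surrogate test

Per structure pair, the cross-spectral density of a trial at an alignment
event is the wavelet coefficient of one channel times the conjugate
coefficient of the other at that single time point. The production
estimator is the debiased WPLI², computed with the O(N) identity
`((ΣI)² − ΣI²) / ((Σ|I|)² − ΣI²)` which equals the pairwise double sum
over `j ≠ k` exactly (acceptance criterion: agreement to 1e−12 against an
independent double-sum evaluation over 10⁴ random draws). It can be
legitimately negative; all-real cross-spectra (purely instantaneous
coupling) make it undefined, returned as `NA` rather than 0 — volume
conduction produces *no evidence*, not evidence of absence. Because
sensitivity depends on trial count, sessions always use exactly the
11th–40th artifact-free trials.

One point where a commonly stated intuition fails: the *debiased*
estimator's expectation does not "grow toward 1 with N" under a fixed
noisy lag — it is approximately unbiased for the population value
`(E[I]/E[|I|])²` at every N (that growth describes the biased estimator).
Our property test asserts the corrected statement: flat mean at the
Monte-Carlo plateau, shrinking SD with N, plateau rising toward 1 as phase
jitter shrinks.

Significance of the connectivity *increase* (time-of-maximal-beta minus
nose-poke-start) uses a two-condition label-exchange scheme: each
surrogate independently swaps, per trial (all frequencies together), the
two events' cross-spectra, and the band-maximum of the recomputed
difference is collected; p is the fraction of 2000 surrogate maxima
strictly above the observed band maximum. Using the maximum over all 23
frequencies corrects for multiple comparisons. Per-trial exchange (rather
than pooled reshuffling) preserves within-trial spectra and is the
standard nonparametric two-condition test; a pooled variant is available
by flag, as is a `(b+1)/(n+1)` smoothed p-value. Type-I error at both 0.05
and 0.01 is an acceptance criterion, checked on 200 exchangeable null
sessions. The per-session **hub index** is the proportion of structure
pairs significant at α = 0.01.

## Behavioral labeling

Whole-session performance counts no-response trials as incorrect. The
learning criterion is ≥ 80% correct on two *consecutive* 30-trial blocks
on three *consecutive* days; blocks partition the session without overlap
by default ("two consecutive blocks" reads most naturally over a
partition), with a sliding variant for sensitivity checks. The first day
of the criterion run becomes LC1, the day before it LC0, earlier days
S1…Sn; labeling is a pure function of the per-day block performances. The
reversal "pre-learning" session is the last one below 60%. The labeler is
verified exhaustively against a brute-force reference over every
satisfaction pattern of up to six days.

## The synthetic generator: what it emulates, and what it does not

Each channel is unit-RMS 1/f^α Gaussian noise (spectral shaping, exact
exponent control; default α = 1) plus, on olfactory channels, a ~2 Hz
respiration-locked sinusoid with slow random-walk frequency jitter, plus,
on beta-expressing channels, one burst per trial: an amplitude-modulated
sinusoid at `beta_freq` (default 25 Hz) under a Gaussian envelope of SD
120 ms centered 150 ms before nose-poke end — placing burst energy inside
the `[−400, +100]` ms analysis window. Burst peak amplitude is
`gain × burst_amp × RMS` (default `burst_amp = 2`, so gain 1 is a
clearly-visible but not dominant burst, within-trial SNR ≥ 1). Coupled
pairs share burst phase up to a configured offset and Gaussian jitter;
uncoupled channels draw independent phases each trial, which the WPLI²
stage must (and does) read as disconnected. Brief broadband artifacts are
90–250 Hz band-limited noise transients of 20–200 ms at a configured
multiple of background RMS, recorded in the ground truth.

Trial structure follows the task: < 2 s sampling, ≥ 7 s inter-trial
interval, balanced pseudo-random odors, Bernoulli correctness given a
latent per-trial performance, licks on rewarded trials. Scenario plans
(`acquisition`, `transfer`, `recall`, `reversal`) set session-level
performance and gain trajectories; within every session both ramp from 30%
to 100% of the session level over the first 15 trials, emulating the
warm-up dynamics seen at criterion. The acquisition plan keeps
pre-criterion days at ≤ 0.65 and at-criterion days at 0.92: the published task
descriptions of learning are only qualitative (~0.5 rising toward ~0.9), and this
separation is what makes the intended criterion day recoverable by the
labeler under Bernoulli noise at block size 30 — a generator design
choice, made once. In the reversal scenario the first session runs *below*
chance (0.25 from trial 6) while gain stays at its learned maximum: the
animal confidently applies the old rule.

What the generator does **not** emulate: spiking activity, conductance
-based LFP biophysics, inter-odor amplitude differences, respiration-phase
coupling of bursts, non-stationary noise floors, or electrode drift. A
green test therefore establishes that the pipeline recovers the *stated*
statistical structure (burst gains, phase coupling, artifact intervals,
criterion days), not that it is robust to every pathology of real
recordings. Real sampling rates (15 kHz) are emulated at 1 kHz by default
(200 Hz when artifacts are not needed): enough to keep the 90–250 Hz
artifact band below Nyquist at desk-scale runtime.

## Numerical choices and degenerate inputs

* All window/epoch intersections are half-open `[start, end)`; window
  sample indices round to the nearest grid point (so a window edge can land
  half a sample early — the tests allow exactly that slack).
* Ties in per-time frequency maxima break toward the lower frequency;
  argmax over maps breaks toward earlier time within the lower frequency.
* `wpli`/`debiased_wpli2` need N ≥ 2 and return `NA` on an identically
  zero imaginary cross-spectrum; `surrogate_test` warns below 100
  surrogates (resolution too coarse for α = 0.01).
* Baselines with zero surviving periods flag the trial undefined;
  `select_trials` errors (naming the shortfall) below 40 clean trials; the
  pipeline logs and skips connectivity for such sessions instead of
  aborting.
* Determinism: every stochastic stage takes a seed; the pipeline spawns
  per-stage child seeds from one master seed, and a rerun with identical
  config is byte-identical (an acceptance criterion). Functions restore
  the caller's RNG state.
* Percentile bootstrap (not BCa) for across-rat CIs: the minimal reading
  of "bootstrap method"; per-rat aggregation always precedes across-rat
  aggregation, and a property test demonstrates on skewed data that naive
  trial pooling would give a different answer.

## Known limitations

* The `sigma` convention cannot be cross-checked against the original
  (non-public) implementation; absolute amplitudes are convention-bound
  even though all ratio-based conclusions are not.
* FIR resampling attenuates slightly near the passband edge (90% of target
  Nyquist) and distorts the first/last filter half-length; both are
  irrelevant at 17–28 Hz analysis on 200 Hz signals but matter if the
  package were pushed toward gamma on marginal rates.
* The surrogate test assumes exchangeability of the two alignment events
  per trial; systematic amplitude differences between events are absorbed
  by WPLI²'s amplitude weighting but extreme non-stationarity is not
  modeled.
* Session I/O uses plain-text CSV/JSON rather than HDF5: this build
  environment has no R HDF5 bindings, and text keeps fixtures portable;
  the layout mirrors the HDF5 design (one dataset per structure, rate and
  identity attributes) so a swap-in backend would be mechanical.
* Mixed-model group inference is deliberately out of scope: the package
  exports tidy per-trial/per-block tables for `lme4`/`afex`-style fitting
  elsewhere.
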