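---
title: "Methods: synthetic mouse EEG and the phenotyping pipeline"
author: "eegpheno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic mouse EEG and the phenotyping pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

eegpheno analyzes chronic frontal EEG + nuchal EMG recordings from mouse
disease models: sleep staging, resting spectral structure, sleep spindles,
auditory steady-state responses (ASSR) and mismatch-negativity (MMN)
event-related potentials, followed by genotype group statistics. Because raw
recordings from such experiments are rarely shareable, the package ships a
ground-truthed synthetic session generator, so every analysis stage can be
validated against known truth. This vignette documents the models, the
defaults and their units, the numerical choices, and what the synthetic
validation does and does not establish.

## The synthetic EEG/EMG model

**Background spectrum.** Each vigilance stage (WAKE, NREM, REM) is described
by an aperiodic component plus oscillatory peaks:

$$P(f) = 10^{b} f^{-\chi} + \sum_j \frac{a_j^2}{\sigma_j\sqrt{2\pi}}
  \exp\!\left(-\frac{(f-c_j)^2}{2\sigma_j^2}\right) \quad [\mu V^2/Hz]$$

with offset $b$ (log10 uV^2/Hz), exponent $\chi$ (dimensionless), and peaks
parameterized by center $c_j$ (Hz), RMS amplitude $a_j$ (uV; the Gaussian
integrates to $a_j^2$ uV^2 of band power) and bandwidth $\sigma_j$ (Hz). The
$1/f^\chi$ law plateaus at 0.5 Hz and rolls off as $(f/0.5)^4$ toward DC,
mirroring the AC-coupled acquisition front end (mouse EEG systems record
through a ~1 Hz hardware high-pass). Gaussian noise with exactly this
spectrum is synthesized by spectral shaping: white noise is Fourier
transformed, multiplied by $\sqrt{P(f)\,f_s/2}$, and inverted. This makes
the generator's spectrum analytically known, which the spectral tests
exploit (Parseval checks, exponent recovery, band-power scaling).

Default stage parameters emulate frontal mouse EEG:

| stage | offset | exponent | peaks (center Hz, RMS uV, sd Hz) | EMG RMS (uV) |
|-------|--------|----------|----------------------------------|--------------|
| WAKE  | 1.2    | 1.5      | theta (7, 6, 1.2), gamma (40, 3, 4) | 40 |
| NREM  | 1.5    | 2.5      | delta (2, 18, 0.8), sigma (13, 3, 1), gamma (40, 2, 4) | 8 |
| REM   | 1.0    | 2.0      | theta (7, 12, 1.2), gamma (40, 2, 4) | 4 |

The steep NREM exponent with a dominant delta peak, theta-dominated REM, a
flatter WAKE spectrum, and the EMG atonia ordering WAKE >> NREM > REM are
the features rodent sleep scoring relies on. EMG is white noise at the
stage RMS.

**Hypnogram.** Stage sequences are semi-Markov on 10-s epochs (the rodent
scoring convention): cycles of WAKE -> NREM -> (REM with probability 0.3)
-> WAKE, with shifted-Poisson bout lengths around configurable means
(defaults 120/120/60 s). Each WAKE bout mean is adapted to steer the
realized NREM fraction to the target, so a session realizes its target
fraction within ~1-2 percentage points rather than drifting with bout-level
noise; this matters because the NREM-fraction contrast between synthetic
cohorts is itself a measured endpoint. Sessions begin with a WAKE bout
covering the requested sleep-onset latency. Infeasible combinations (target
fraction unreachable given the bout means and latency) raise an error
rather than silently missing the target.

**Spindles.** Sleep spindles are Hann-enveloped sinusoids at 9/11/13/15 Hz
inserted during NREM only, with Poisson counts per bout (default rates
2/3/3/2 events per NREM minute), durations uniform on 0.6-1.5 s, and 25 uV
peak amplitude against the ~1-2 uV sigma-band background. Placement
enforces a 1-s minimum gap between same-frequency events (thalamocortical
spindle generation is refractory on this timescale) using retry sampling,
so the realized event rate stays proportional to the nominal rate across
cohorts: a rejection-based placement would thin denser cohorts more and
compress injected rate contrasts. Events that cannot be placed are counted
in the `skipped` attribute.

**Auditory sessions.** ASSR sessions present click-train surrogates —
sinusoids at the stimulation frequency (10-50 Hz), amplitude equal to
`entrainment_gain` (default 0.15) times the background RMS — in randomized
order over a quiet-wake 1/f background, 1-s trains with a 1.5-s
inter-train interval. MMN sessions present standard and deviant tone
events (default 900/100) at a fixed 0.6-s ISI; deviants are placed in
distinct inter-standard gaps so no two deviants are adjacent. Each event
adds its condition's ERP template: Gaussian components P1 (+, 25 ms, 8 ms
SD), N1 (-, 60 ms, 15 ms SD), P3a (+, 180 ms, 40 ms SD). The standard
condition carries no P3a — P3a is modeled as a novelty-specific component —
so the deviant-minus-standard difference waveform carries the full P3a and
a deviant P3a scaling maps one-to-one onto the difference-waveform P3a.
Stimulus latencies and ISIs are declared defaults of this package, chosen
as mouse-typical values; they are deliberately config-exposed because
published paradigms vary.

**Effect injection.** `effect_config()` carries five multiplicative
scalings: `gamma_amp` (spectral amplitude in 30-50 Hz, so band power scales
by its square), `spindle_rate`, `assr_gain`, `p3a_amp` (deviant P3a
amplitude) and `nrem_fraction` (hypnogram target). `effect_presets()` bundle
them into genotype contrasts of published magnitude: the *grin2a*-like
preset (gene dose-dependent gamma increase of +10/+20% power, spindle
increase, ~30% reduction of 50 Hz ASSR excess ratio) and the *akap11*-like
preset (dose-dependent spindle reduction of -25/-62.5%, -10% NREM, -70%
deviant P3a in the homozygote).

**Reproducibility.** Every generator takes a seed; all draws flow from it
through `with_seed()`, which restores the caller's RNG state. Fixed seed in,
bit-identical session out.

## Signal I/O

Recordings move on disk as EDF (the open polysomnography standard; the
acquisition vendor's native format is proprietary and out of scope): 16-bit
data records of one second, physical scaling per channel. The writer rounds
each channel's physical range up to 3 significant digits so the 8-character
ASCII header field represents it exactly; round-trip error is then bounded
by half a quantization step (~2^-16 of the range). The reader validates
header arithmetic and fails loudly on truncation. Event tables and
hypnograms are tab-delimited text.

Filtering is 4th-order Butterworth applied forward-backward (zero phase),
the standard EEG practice; no notch filter is applied anywhere. Epoch
grids are 0-based half-open sample intervals, `[k L f_s, (k+1) L f_s)`,
with trailing partial epochs dropped.

## Sleep staging

Per 10-s epoch, features are: log band powers (delta 1-4, theta 4-8, sigma
12-15, gamma 30-50 Hz) from within-epoch Welch spectra (2-s windows, 1-s
overlap), the theta/delta ratio, EMG RMS, and spectral entropy. The
classifier is a transparent rule cascade with per-recording adaptive
thresholds, chosen over a trained model so behavior is deterministic and
auditable:

1. epochs whose EMG RMS exceeds the WAKE threshold are WAKE;
2. remaining (sleep) epochs with theta/delta > 1.5 and sigma power below
   the sleep-epoch median are REM;
3. the rest are NREM;

followed by a 3-epoch majority smoother and relabeling of REM that
immediately follows WAKE (REM onset from wake does not occur in healthy
rodents).

The WAKE threshold deserves a note. A fixed EMG quantile (e.g. the 60th
percentile) mislabels approximately |wake fraction - (1 - quantile)| of all
epochs whenever the animal's true wake fraction differs from the quantile's
complement, because the EMG distribution is strongly bimodal and a fixed
quantile then lands inside one of the clusters. That bias propagates
directly into %NREM, the pipeline's headline sleep metric. The default is
therefore the midpoint of a deterministic two-means split of log EMG RMS,
which adapts to any wake/sleep ratio; the quantile rule remains available
(`threshold_method = "quantile"`). If the two EMG clusters differ by less
than a factor of 2 the distribution is treated as unimodal and all epochs
are called WAKE — the conservative interpretation, since an animal that
truly sleeps produces unmistakable EMG bimodality.

Sleep metrics over a light-cycle window (default: first 12 h): stage
percentages, sleep-onset score (% of epochs asleep — NREM or REM — in the
first hour), per-stage bout counts and mean lengths, and transitions per
hour.

## Spectral analysis

`welch_psd()` averages Hann-tapered, demeaned segment periodograms,
normalized so the density integrates to the signal variance. Resting-state
spectra average per-epoch Welch spectra (4-s windows, 2-s overlap within
each 10-s epoch) over all epochs of a stage; ASSR uses the 0.5-s/0.25-s
parameters of that paradigm. Tapering and demeaning trade the exact
discrete-Parseval identity for leakage control; the exact identity holds
for a rectangular single-segment spectrum (`taper = "rect"`), which is what
the Parseval test asserts. Band power is the trapezoidal integral over
[low, high) with interpolated band edges; bands are slow 0.5-1, delta 1-4,
theta 4-8, alpha 8-12, sigma 12-15, beta 15-30, gamma 30-50 Hz.

Spectral entropy is the Shannon entropy of the probability-normalized
density over 0.5-50 Hz divided by log of the bin count: 1 for a flat
spectrum, 0 for a single occupied bin, invariant to rescaling.

The aperiodic fit uses the knee-free model $\log_{10} P = b - \chi
\log_{10} f$ (only an exponent is reported for this assay, so the knee
parameter is omitted): an ordinary line fit in log-log space, Gaussian
peaks fitted to residuals exceeding 2 residual SDs (largest first, at most
4, Nelder-Mead refinement), then an aperiodic refit on bins more than 2
peak-SDs away from any fitted peak. Fit range defaults to 1-50 Hz. On
shaped-noise spectra the exponent is recovered with RMSE below 0.2 across
$\chi \in \{0.5, 1, 2, 3\}$, and a strong 10 Hz peak does not bias it —
both are asserted in the test suite.

Phase-amplitude coupling uses the modulation-index formulation: phase from
the analytic signal of the slow band, amplitude envelope from the fast
band, mean amplitude binned into 18 phase bins and normalized to a
distribution P, MI = (log N - H(P))/log N. Defaults pair delta/theta phase
(2-6 Hz) with gamma amplitude (30-50 Hz), the canonical parameterization;
band pairs are arguments, and no claims are made about specific pairs.

## Spindle detection

A median-relative two-threshold envelope detector, robust to amplitude
scaling across subjects. Per center frequency (9/11/13/15 Hz): bandpass to
center +/- 1 Hz (so the four bands do not overlap), analytic-signal
envelope, 0.2-s moving-RMS smoothing. Samples above 3x the median NREM
envelope seed events; boundaries extend to the 1.5x-median crossing;
events closer than 0.3 s merge; events survive if 0.5-3 s long and fully
inside NREM. Three numerical refinements matter on realistic signals:

- the boundary threshold is floored at 25% of the event's own peak
  envelope, because with a quiet background the 1.5x-median contour lies
  inside the bandpass filter's ringing tails and would smear onsets by
  hundreds of milliseconds;
- each seed run must have an envelope-weighted instantaneous frequency
  within +/-1 Hz of the center, and
- must carry more envelope in its own band than in either flanking band
  (center +/- 2 Hz computed over the event, the "flank veto"); a burst at a
  neighbouring spindle frequency leaks through the bandpass skirts with
  enough energy to cross a median-relative threshold, and both vetoes run
  before boundary extension and merging so leakage can neither survive nor
  contaminate a true event's boundaries.

Density is events per NREM minute, normalized by light-cycle NREM time
only. All constants are arguments.

## Evoked analyses

Epoching slices a window around each event onset, subtracts the per-trial
baseline mean (default -50-0 ms for ERP work), drops trials that would
cross a recording edge, and rejects trials exceeding 400 uV absolute (all
config-exposed). The ASSR statistic is the ratio of trial-averaged Welch
power at the stimulation frequency bin, evoked (0.2-1 s) over baseline
(-0.5-0 s), with 0.5-s windows and 0.25-s overlap. PSDs are averaged across
trials before the ratio is formed — the lower-variance of the two
averaging orders. The ratio is scale-invariant and equals 1 in expectation
without stimulation.

ERP analysis averages per condition, forms the deviant-minus-standard
difference waveform, and reads P1 (maximum in 10-50 ms), N1 (minimum in
30-100 ms after the found P1) and P3a (maximum in 100-300 ms after the
found N1); the windows are mouse-typical defaults. A component is flagged
absent when its extremum has the wrong sign or sits on the boundary of its
search window (a monotone segment has no interior extremum). Peak picking
on a noisy average is biased upward by the maximum over the window; with
the default trial counts (900/100) this bias is small relative to the
component amplitudes, and it largely cancels between cohorts compared at
the same trial counts.

## Group statistics

One-way ANOVA is computed from the between/within sums of squares with the
p-value from the F distribution; Tukey HSD uses the Tukey-Kramer
studentized-range statistic $q = |\bar y_i - \bar y_j| / \sqrt{MSW/n_h}$
($n_h$ the pair's harmonic mean size) with adjusted p from `ptukey()`,
base R's numerical quadrature of the studentized-range distribution. Both
are cross-checked in the tests against `aov()`/`TukeyHSD()` as independent
oracles, the family-wise error rate is verified at ~5% on a simulated null,
and ANOVA p-values are verified uniform under the null. Percent change is
relative to the WT group mean. No correction is applied across metrics or
frequency bands — tests are reported per band, and this is deliberate;
users comparing many bands should apply their own correction.

## Study orchestration and problem sizes

`make_demo_study()` writes EDF + event + ground-truth files and a YAML
config for n subjects per genotype; `run_study()` re-reads everything from
disk, runs staging (blind to ground truth), spectra, spindles, ASSR and MMN
per subject, then per-metric ANOVA/Tukey/percent-change tables, a summary
and a run log that records every resolved parameter. Subject failures are
logged and skipped; the report status then reads "partial".

Desk-scale defaults keep everything laptop-sized: 1-h sleep sessions
(full-length sessions are a config choice), and the test suite further
shortens sessions (10-40 min) and reduces the sampling rate to 250-500 Hz —
the physics (band placement, SNR, rates) is unchanged. The acceptance
script runs the five effect recoveries at 1000 Hz with 12 subjects per
cohort: 1-h sleep sessions for the gamma and %NREM contrasts, 50-min
NREM-rich sessions for spindles, 700 trials at 50 Hz for ASSR (the
baseline estimate gets one 0.5-s segment per trial, so trial count is what
controls its convergence), and 900/100-trial oddball sessions for P3a.

## What the synthetic validation shows — and what it does not

Passing tests establish that each stage recovers what was injected under
the generator's assumptions: Gaussian 1/f-plus-peaks backgrounds,
stage-homogeneous bouts with epoch-aligned boundaries, spindles as clean
enveloped sinusoids, stationary noise, no artifacts. Real recordings
violate all of these at some rate: movement and chewing artifacts,
electrode drift, state transitions inside epochs, spindles with chirp and
asymmetric envelopes, and non-sinusoidal theta. The staging accuracy
(>= 90%), spindle F1 (>= 0.8) and effect-recovery figures measured here are
therefore upper bounds on real-data performance, not estimates of it. What
the synthetic route does establish is the absence of systematic pipeline
biases: a null injection stays null (ANOVA at nominal alpha), and injected
contrasts are recovered at their injected magnitude rather than compressed
or inflated.

## Known limitations

- The staging cascade assumes EMG bimodality; recordings with broken EMG
  electrodes are called all-WAKE rather than guessed.
- 9 Hz spindle detection borders the theta band; on real data theta bursts
  will inflate its false-positive rate more than the synthetic background
  suggests.
- The aperiodic model is knee-free; spectra with a clear knee need the fit
  range restricted above the knee.
- The MMN generator's fixed ISI and component set do not model habituation
  or latency jitter.
- Group statistics assume one value per animal (no repeated-measures
  structure across ages).
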