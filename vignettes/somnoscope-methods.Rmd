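---
title: "somnoscope: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{somnoscope: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

somnoscope analyses continuous rodent EEG/EMG telemetry of the kind
acquired by implanted wireless transmitters: EEG and EMG at 500 Hz
(hardware band 0.1–100 Hz) and an activity channel at 200 Hz, recorded for
24–72 h in the home cage under a 12:12 light–dark schedule.  Five analysis
stages share one `recording` container: Welch spectral band powers with
total/relative delta summaries, amplitude-threshold epileptiform spike
counting, rule-based four-state sleep staging with light–dark architecture
metrics, automated sleep-spindle detection, and a group-comparison layer.
A synthetic generator produces recordings with known ground truth so that
every detector is validated by recovery rather than by fiat.

## Spectral analysis

Power spectral density uses Welch's method: Hann-windowed overlapping
segments, averaged one-sided periodograms.  The segment length (4 s) and
overlap (50%) are not dictated by the procedure being reproduced; 4-s
segments give 0.25 Hz resolution, enough to resolve the 0.5 Hz lower delta
edge.  Bands follow the conventional rodent scheme — delta [0.5, 4), theta
[5, 9), alpha [9, 12), beta [13, 30), gamma [30, 50] Hz.  The scheme
leaves gaps at [4, 5) and [12, 13) Hz; we preserve them rather than bridge
them, because total power is defined directly over 0.5–50 Hz.  The shared
9 Hz edge goes to alpha under the half-open rule.

Band power is a literal *sum of density bins*, not a trapezoidal
integral, because the procedure it reproduces adds the density data; an
`integrate = TRUE` flag multiplies by the bin width for users who want
physical units.  Total delta power sums the delta bins; total power sums
0.5–50 Hz inclusive; relative delta is their ratio, a scale-free quantity
(invariant under amplitude scaling to 1e-6 in the acceptance suite).

Light–dark spectra cut the recording into maximal runs of same-cycle
seconds and accumulate Welch periodograms per run, so no segment ever
straddles a cycle boundary.  The light cycle is clock [7, 19); the source
material's figure caption states the opposite mapping, but its Methods
text and the vivarium schedule (lights on 7 a.m.–7 p.m.) agree on this
one, so the Methods mapping is used.

## Spike detection

The spike counter is a two-pass amplitude rule: 30-s windows; per-window
mean and SD of the *signed* samples; candidates beyond 2.5 SD either side
of the window mean; confirmation when the three samples before the
candidate rise strictly toward it and the three after fall strictly away
(mirrored for negative excursions, ties rejected); windows containing any
activity above 0 counts are excluded as movement artifact; the first and
last 3 h are trimmed.  Confirmed candidates closer than 20 ms are merged
into one event (an extension beyond the published rule, to avoid
double-counting a single biphasic transient; configurable).

Two deliberate readings, both exposed as parameters: the SD is computed
once per window, candidates included (the procedure describes a single
first pass); and the activity threshold is zero — any detected movement
excludes the window, the strictest reading.

Detection runs on the unfiltered trace.  The published pipeline's 0–50 Hz
bandpass is described with the spectral preprocessing, and the spike pass
itself lists no band-limiting step.  This matters: on a signal band-limited
to 50 Hz and sampled at 500 Hz, *every* oscillation peak is locally
monotone over three samples, so the flank confirmation would pass almost
any >2.5 SD background peak.  On a raw trace with a broadband noise floor
the flank rule does real work.  Even so, a 2.5 SD two-sided threshold on
an approximately Gaussian signal flags ~1.24% of samples, so the detector
has a substantial background event rate by construction; the acceptance
suite therefore measures the noise floor on spike-free simulations and
requires it to stay within an order of magnitude of the Gaussian-tail
candidate expectation, and validates the detector proper by recall of
injected high-SD transients (with precision reported, not gated).

Counts from recordings of different lengths are never comparable, so the
result object always carries `rate_per_h` over the artifact-free windows
alongside the raw count.

## Sleep staging

Staging quantifies the standard qualitative rules: active wake = high EMG
tone; wake = low-amplitude, broadband EEG with low tone; slow-wave sleep =
high-amplitude, delta-dominant EEG with low tone; paradoxical sleep =
low-amplitude, theta-dominant EEG with low tone.  Each second gets EEG
RMS, delta power, theta power, total power and EMG RMS; a decision tree
labels it; 10-s epochs take the per-second majority when the modal label
covers at least 50% of the epoch *and* is the unique mode — a 5 s/5 s tie
has no unique majority and the epoch is left unscored, as is any epoch
whose winner falls short of 50%.

Implementation notes that matter:

* Band powers come from Butterworth band-filtered copies of the trace
  (per-second mean square), not from 1-s periodograms.  At 1 Hz
  resolution a periodogram's delta band is three bins wide; binning and
  leakage bias the delta fraction down by ~0.15 and inflate its variance.
* Amplitude and EMG thresholds are multiples of the recording-wide
  *median* per-second RMS, making staging invariant to global amplitude
  scaling.  The median sits in the low-amplitude cluster as long as
  slow-wave sleep occupies less than half the recording, which holds for
  any realistic stage mix.
* Thresholds are this package's calibration, fixed once against simulator
  ground truth: `amp_high_mult = 1.5`, `emg_high_mult = 2.0`,
  `delta_frac_min = 0.35`, `theta_over_delta_min = 2.0`.  The delta
  fraction floor is deliberately below the nominal slow-wave delta
  fraction (~0.7) because a 1-s estimate of a 3.5-Hz-wide band power has
  roughly 7 chi-square degrees of freedom (relative SD ~0.5); a floor at
  0.5 would reject a fifth of genuine slow-wave seconds.  Misclassifying
  wake as slow-wave sleep is still blocked by the amplitude gate.  With
  this calibration, epoch agreement with ground truth on default
  simulations is ~99% (the acceptance bar is 90%).

Architecture metrics: mean bout duration per state (a bout is a maximal
run of identical non-unscored epochs; an unscored epoch terminates a
bout); sleep latency (mean over every wake-class run followed by sleep of
the time from run onset to sleep onset; both wake states are eligible
origins), reported both to any sleep state and to paradoxical sleep
specifically; and total sleep time.  Latencies with no qualifying
transition are missing, never zero.

Two-hour bins are clock-aligned starting at midnight; a complete bin holds
720 ten-second scores, and percent time divides by 720 (by the actual
epoch count in flagged partial bins; an alternative `percent_scored`
denominator is also emitted).  Unscored epochs are counted as artifact in
the 720 denominator.  Each bin is labeled light or dark by its starting
clock hour, so the 6–8 bin belongs to the dark cycle and 18–20 to the
light cycle under the [7, 19) schedule.

## Spindle detection

The detector reproduces a published cubed-RMS thresholding procedure
literally: a 4th-order 10–15 Hz Butterworth bandpass, in cascade with a
second Butterworth band design specified by its corners (3 Hz and 22 Hz
stopbands, 10 and 15 Hz passbands, 24 dB attenuation; the order solver
gives 3, i.e. a 6th-order bandpass), both zero-phase; a 750-ms sliding RMS
envelope; pointwise cubing; then a lower threshold at 1.2x and an upper
threshold at 3.5x the mean cubed envelope.  A spindle is a maximal
interval above the lower threshold whose peak exceeds the upper threshold
and whose duration is strictly between 0.5 and 10 s.  The cascade is
partially redundant — that is faithful to the procedure.  The threshold
baseline is the global mean over the supplied trace (the procedure names
no baseline window); detection runs over the whole recording with no
stage restriction, and both choices are configurable.

Because the thresholds are data-relative, detection is invariant to
amplitude scaling, and the baseline rises with the recording's spindle
content — on spindle-rich slow-wave sleep this self-normalisation is what
keeps the false-alarm rate low.  On stage-heterogeneous recordings the
sigma-band background differs between states, and background fluctuations
in slow-wave sleep produce genuine threshold crossings; these count as
detections of the procedure, not bugs, and the recovery criterion is
therefore evaluated on slow-wave-rich recordings.

## The synthetic world

The generator emulates exactly the structure the analyses assume, no
more.  A semi-Markov chain alternates the four stages with
truncated-exponential bout dwells (10-s floor so every bout is scorable;
means default to 150 s active wake, 300 s wake, 180 s slow-wave, 60 s
paradoxical — typical reported mouse architecture), paradoxical sleep
reachable only from slow-wave sleep (entry probability 0.5), and wake
dwell doubled during dark hours.  EEG is a sum of three unit-RMS noise
components — delta band (0.5–4 Hz), theta band (5–9 Hz), and a broadband
component spanning the 100 Hz acquisition bandwidth — mixed with
stage-dependent weights and amplitudes (120 uV RMS slow-wave, 50 uV
otherwise; amplitudes are free parameters, as the source reports none),
plus a 5 uV white sensor-noise floor.  The band components use 4th-order
edges so that "delta" has no visible energy at 11 Hz; with 2nd-order
skirts, a doubled delta gain measurably contaminates the spindle band,
which no genuine 0.5–4 Hz rhythm would.  EMG is white noise at 60/10 uV
RMS (active wake/other); activity is Poisson counts, nonzero exactly in
active-wake seconds.

Spikes are 40-ms biphasic (one-cycle sine) transients at Poisson times
outside active wake, amplitude 6 background SDs — the template satisfies
the 3-point flank confirmation at 500 Hz by construction.  Spindles are
Hann-windowed 11 Hz sinusoids placed without overlap inside slow-wave
bouts at 2 per slow-wave minute, 0.8–2 s, with in-band amplitude 4x the
slow-wave sigma-band background (computed analytically from the component
filters' frequency responses); a spindle drawn against the end of its
bout is shortened to fit, never dropped from the log.  Cohorts use
deterministic per-animal seeds (`seed + animal index`).  The "affected"
group effect multiplies delta gain, scales *both* the paradoxical dwell
and the slow-wave-to-paradoxical entry probability (the phenotype is
fewer *and* shorter paradoxical bouts; scaling dwell alone would leave
entry frequency, and hence latency, untouched), and scales the spindle
and spike rates.

What the generator does **not** emulate — and hence what a green test
does not establish: 1/f-shaped spectra, circadian drift beyond the binary
dwell bias, seizure events, EEG artifacts other than movement (captured
only via the activity channel), state-transition dynamics inside a
second, or any calibration to the unreleased recordings behind the
procedure.  Recovery results say the pipeline implements its rules
correctly, not that the rules are optimal on real data.

## Statistics

Group comparisons use the classical pooled-variance Student t (Welch by
flag), matching the reported tests; the Holm–Sidak step-down adjustment
is applied across the five frequency bands; correlations use ordinary
least squares with the F test on the slope.  The proprietary ROUT outlier
screen is replaced by a documented approximation — median/MAD robust z
scores screened by Benjamini–Hochberg at Q — which only flags, never
removes.  Type-I error of the t test and uniformity of null regression p
values are checked by simulation in the acceptance suite.

## Scale of the acceptance simulations

The direction-recovery criterion simulates 20 replicate cohorts of 7
affected vs 5 control animals.  Full-length (24–72 h) recordings are far
outside the test-time budget, so cohort animals are simulated for 1.5 h
starting at lights-on.  That length is a power decision, made before the
criterion was run: with ~4 paradoxical bouts per hour and exponential
dwells, per-animal mean-bout SE scales as mean/sqrt(bouts), giving a
noncentrality around 3 for the halved-dwell comparison at n = 7 vs 5 —
about 85% power — while 1 h would drop below 70%.  Two directions cannot
reach the 80% bar at any affordable scale, and one is inverted, for
structural reasons analysed in the repository notes: total sleep time
changes only by the (small) paradoxical share under the stated effect
set; spindles per sleep hour moves *down*, not up, when the spindle rate
is halved but sleep time barely falls; and the spike count direction is
dominated by the detector's background-peak floor, which decreases as
delta gain rises.  These expectations are asserted as stated and left
failing rather than weakened.

## Numerical and edge-case choices

* Butterworth design (analog prototype, band transform, bilinear
  transform) and zero-phase filtering are implemented in C++ and verified
  against independently computed reference coefficients frozen in the
  test suite; zero-phase filtering uses odd-reflection padding of three
  filter orders.
* Time is seconds from recording start; intervals are half-open
  `[start, end)`; clock hours are modulo 24.
* EDF storage is 16-bit; round trips are exact to one quantization step
  of the written physical range.  Writing truncates to whole seconds.
* The sliding RMS envelope shrinks its window at the trace edges, so
  envelope length always equals signal length.
* Degenerate staging input (zero EEG power) is unscored unless EMG tone
  is high (high tone is active wake regardless of EEG).
* `detect_spindles` on a flat zero envelope returns an empty table; a
  spindle rate denominator of zero yields a missing rate, except that
  zero spindles in zero sleep is reported as rate 0.
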