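---
title: "Cardiorespiratory sleep staging from chest-worn accelerometry: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiorespiratory sleep staging from chest-worn accelerometry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accelsleep)
```

## The measurement model

A triaxial accelerometer on the chest records three superimposed
phenomena at very different amplitudes and time scales:

* **gravity and posture** — a near-unit vector that changes slowly as
  the sleeper shifts position;
* **respiration** — a small periodic tilt of that vector (fractions of
  a degree to a few degrees) as the chest wall rises and falls;
* **heartbeats** — the seismocardiographic pulse: a millisecond-scale,
  milli-g transient repeated once per cardiac cycle;
* **gross body movement** — broadband, high-amplitude bursts.

The pipeline separates these by scale and converts them into the two
inputs that autonomic sleep staging needs — an instantaneous heart rate
(IHR) and a respiratory effort signal — plus per-second activity counts
that quantify movement.

Sleep staging from these inputs is possible because autonomic state
tracks sleep depth: heart rate falls and stabilizes in deep non-REM
sleep, REM is autonomically unstable with large heart-rate variability,
and breathing is most regular in N3 and most irregular in REM. The
classifier works on 30-s epochs over the four classes Wake, N1+N2
(light sleep), N3 (deep sleep) and REM, coded `W`, `L`, `D`, `R`.

## Extraction chain

**Channel collapse.** The three channels are summed sample-wise. The
cardiac pulse projects onto all axes, so the sum preserves it
regardless of sensor orientation while halving no information that the
beat detector needs.

**Beat localization.** The collapsed signal is band-passed to 5--20 Hz,
where the cardiac transient lives, and its rectified, low-passed
envelope is peak-picked. Beats are the subsequence of candidate peaks
maximizing

\[
\sum_i \big(a_i - c\big)\; -\; w \sum_i \big(\mathrm{IBI}_{i+1} -
\mathrm{IBI}_i\big)^2 ,
\]

subject to every inter-beat interval lying in 0.33--2 s (30--180 bpm).
Here \(a_i\) is the envelope amplitude normalized so a typical cardiac
peak is ~1, \(w = 10\) is the smoothness weight, and \(c = 0.4\) is a
per-beat acceptance cost. The cost term matters: without it the
maximizer profits from inserting every admissible low-amplitude peak
(more positive terms, near-zero smoothness penalty at regular spacing)
and returns double-rate beat trains. The exact maximizer is found by
dynamic programming whose state is the last *edge* (previous beat,
current beat), since the smoothness penalty couples consecutive IBIs.

Amplitude normalization is robust to movement: envelope peaks beyond
20 times the median peak height are excluded before taking the 90th
percentile as the scale, because a single movement burst otherwise
dwarfs the cardiac amplitude and silences the detector.

**Beat quality and IHR gaps.** Each beat carries a quality score in
\[0, 1\]: the autocorrelation peak ratio of the envelope in a ±5-s
window, searched over lags in the admissible IBI range. The envelope
used here is smoothed harder (3 Hz low-pass) than the detection
envelope, because physiological IBI jitter smears the autocorrelation
peak of narrow spikes. The raw ratio saturates near 0.5--0.6 on clean
signal, so it is rescaled by a factor calibrated once on clean and
pure-noise simulations (division by 0.5, clipped to 1): clean cardiac
signal then scores ~0.97 and white noise ~0.37. IHR samples governed by
beats with quality below `q_min = 0.5` are masked invalid — the
characteristic gap at a movement artifact.

IHR itself is \(60/\mathrm{IBI}_i\) bpm, held constant on each beat's
interval and sampled at 10 Hz; samples outside beat coverage are
invalid.

**Respiratory effort.** The channels are low-passed and decimated to
10 Hz, unit-normalized into orientation vectors, and split into a
vertical component along the slowly varying gravity direction (0.05 Hz
low-pass of the unit vectors) and two horizontal components — the
"bubble coordinates" of a planar spirit level. The respiratory tilt is
recovered by projecting the horizontal pair onto its locally dominant
direction (principal axis of the covariance in a sliding 60-s window),
band-passing to the 0.1--0.7 Hz respiratory band, and normalizing to
unit interquartile range per 5-min block. This estimator is a
transparent stand-in honoring the same contract as a learned effort
model (10 Hz orientation in, 10 Hz effort out), so a trained network
can replace it without touching anything downstream.

**Activity counts and ResAct.** Per full second, activity is the mean
absolute deviation from the within-second mean, summed over the three
channels. The counts are scaled, sample-and-hold upsampled to 10 Hz and
mixed back into the effort signal as
\(\mathrm{ResAct} = (1 + \mathrm{act\_scale}\cdot\mathrm{Act})\cdot
\mathrm{Res}\); the offset by 1 leaves quiet periods untouched. The mix
restores the movement artifacts a thoracic belt would show, which the
downstream classifier expects. `act_scale = 220` was fixed once so the
95th percentile of scaled activity on a calibration night is 5;
whether such scaling should be global or adaptive is genuinely open,
so the value lives in the configuration, not the code.

## Clock synchronization

Two devices recording the same night disagree by a clock offset *o* and
rate *r* (crystal clocks: \(|r-1| < 10^{-3}\)). Both devices see the
same heart, so the IBI series is the shared fingerprint: each series is
rendered as a tachogram (IBI held over its interval, sampled at 2 Hz),
and the affine model \(t' = o + r\,t\) is chosen to maximize the
product-moment correlation over the mutually valid overlap (minimum
5 min; gaps are excluded pairwise, not imputed).

The search is a coarse grid (1 s × 1e-4 steps over ±120 s ×
0.999--1.001, sized so the main correlation lobe cannot be skipped)
followed by two tenfold refinements. Each refinement window spans *two*
parent-grid cells because offset and rate errors trade off along a
ridge (a rate error of \(\delta r\) mimics an offset error of
\(\delta r \cdot t\) mid-recording), and the coarse argmax can sit a
cell or two off the joint optimum. Tachograms whose IBI spread is below
1 µs are treated as degenerate (score 0) rather than correlated:
floating-point jitter otherwise produces spurious ±1 correlations. A
flat coarse surface (max − median < 0.05) raises a low-confidence flag;
a heart rate without variability cannot anchor a correlation.

## Staging

Each 30-s epoch yields a feature record: IHR mean, SD, range, RMS of
successive differences, spectral power in the 0.04--0.15 and
0.15--0.4 Hz bands and their ratio; ResAct dominant respiratory
frequency in 0.1--0.7 Hz, spectral peakedness and amplitude coefficient
of variation; summed activity; and the invalid-IHR fraction. Each
feature also gets a ±2-epoch context average. Epochs with under 50%
valid IHR have their IHR features set missing and are flagged.

The classifier is deliberately transparent: a regularized multinomial
linear scorer over standardized features provides per-epoch class
scores, and whole-night context comes from most-probable-path (Viterbi)
decoding under a stage-transition matrix estimated from the training
hypnograms with add-one smoothing. Reported per-epoch probabilities are
forward-backward posteriors. The decoded path and the posterior argmax
can rarely disagree (joint vs marginal optimum); the labels follow the
path, which is why probabilities are attached as auxiliary output
rather than re-derived. Missing-feature epochs receive uniform
emissions, so their label comes from temporal context alone — no
imputation — and they stay flagged in the output.

This surrogate honors the input/output contract of the deep
cardiorespiratory stagers it stands in for (10 Hz signals in, per-epoch
four-class probabilities out, whole-recording context) while remaining
trainable in seconds on a desktop. It makes no claim of matching their
clinical accuracy; the held-out property gate in the test suite
(four-class kappa > 0.4 on simulated nights) checks that the surrogate
plus feature chain learns the encoded physiology, nothing more.

## Evaluation battery

Agreement is computed per recording for four-class, three-class (N1+N2
and N3 merged into NREM) and each one-vs-rest task: Cohen's kappa,
accuracy, and for binary tasks sensitivity, specificity and PPV, with
undefined denominators reported missing rather than zero. Confusion
matrices report reference-row percentages. Kappa on a single-class
degenerate recording is 1 with a `degenerate` flag when agreement is
perfect (the chance-agreement denominator vanishes).

Sleep metrics use 0.5-min epochs: sleep onset is the first non-Wake
epoch (the recording start is the reference point; lights-off is not
modeled), sleep latency the onset index × 0.5 min, TST the non-Wake
count × 0.5, WASO the Wake count after onset, stage-R latency the first
REM epoch relative to onset, and sleep efficiency TST over total
recording time. "Percentage of TST in Wake" is time-in-Wake / TST ×
100, mirroring the convention of published sleep-statistics tables even
though Wake is not part of TST — the definition is stated here
precisely because it is not self-consistent. Method-comparison error is
estimate − reference, summarized by median and quartiles plus 95%
limits of agreement (mean ± 1.96 × sample SD, *n*−1).

Stage intervals with gap tolerance *M* formalize "a REM period": target
runs separated by at most *M* non-target epochs are merged; intervals
start and end on target epochs; *M* = 20 (10 min) is the conventional
choice for overnight REM/N3 periods. Matching between reference and
estimated interval sets counts shared-epoch overlaps, with one-to-one
pairing by greatest overlap and earliest-first tie-breaks.

Cohort factor influence uses a two-sided Mann–Whitney U test for binary
factors (exact for tie-free groups up to 8, normal approximation with
tie correction otherwise), Spearman rank correlation for continuous
ones, and joint Benjamini–Hochberg control at FDR 0.05. Cohort
summaries report both mean ± SD and median {Q1, Q3}, choosing the
primary form by a Shapiro–Wilk test at α = 0.05 (the presentation
convention of the field's result tables never names a test; this is our
concrete choice).

## The simulator: what it emulates, and what it does not

The generator draws a hypnogram from a first-order Markov chain (the
shipped default favors long N1+N2 runs, sustained N3/REM periods and
brief awakenings, starting in Wake), then conditions physiology on the
stage sequence:

| parameter | W | L | D | R | units |
|---|---|---|---|---|---|
| mean heart rate | 70 | 62 | 57 | 66 | bpm |
| IBI successive-difference SD | 0.050 | 0.035 | 0.020 | 0.060 | s |
| respiratory rate | 0.27 | 0.23 | 0.21 | 0.28 | Hz |
| respiratory rate jitter | 0.08 | 0.03 | 0.02 | 0.12 | fraction |
| movement bursts | 2 | 0.2 | 0.05 | 0.15 | /min |

These are literature-plausible round numbers chosen once — no published
cohort values exist for this parameterization — and they encode the
qualitative physiology the stager exploits: Wake/REM IBI variability
strictly above N3 (enforced by the constructor), breathing more regular
in NREM, movement concentrated in Wake. The waveform model adds a
slowly drifting gravity vector, a small-angle (≤ 5°) sinusoidal
respiratory tilt, one Gaussian-windowed sinusoidal pulse per beat
(carrier 15 Hz, envelope SD 15 ms, so its energy sits inside the
detector's 5--20 Hz band), raised-cosine-ramped broadband bursts inside
movement intervals, and white sensor noise (default cardiac amplitude
0.01 g at noise SD 0.001 g). One root seed derives an independent child
stream per component, recorded in the output.

What the simulator does **not** model: apnea events, arousals,
position-dependent signal amplitude, sensor detachment, multi-night
circadian structure, or any realistic seismocardiographic morphology —
the pulse is just a short detectable transient. Consequently, passing
tests demonstrate that each algorithm recovers what the generative
model put in (beat times, respiratory rate, clock skew, stage-dependent
statistics); they say nothing about clinical accuracy on real
recordings, where the held-out staging kappa of a linear surrogate
would be far below what the near-noiseless simulation yields.

## Numerical choices and problem sizes

Filters are zero-phase Butterworth (forward-backward), applied after
mean removal with the mean restored for low-passes, so constant inputs
pass through exactly and edge transients stay small. Decimation uses a
0.4 × target-rate cutoff, below the 0.45 anti-aliasing bound. Spectral
epoch features use 4× zero-padded periodograms (~0.008 Hz bin spacing
at 10 Hz). The orientation's horizontal basis is the normalized
projection of the device x-axis onto the plane orthogonal to gravity
(any fixed orthonormal pair works — the effort estimator is
rotation-covariant in the horizontal plane); samples below 0.1 g norm
are invalid. Trailing partial windows (seconds, epochs) are dropped,
never padded.

The test suite sizes its simulations for a desktop run: 30-min
recordings for beat detection, a 1-h beat series with 20 random skew
draws for synchronization recovery, and 30 training + 10 held-out
8-h nights (bundle-level, skipping waveform synthesis) for the staging
gate. The acceptance script reruns the same computations from scratch
with seeds derived from its `--seed` argument.

## Known limitations

* The linear stager saturates the simulator (kappa ≈ 1) precisely
  because the generative physiology is cleanly separable; it is a
  contract surrogate, not a clinical classifier.
* Beat detection assumes the cardiac transient dominates the 5--20 Hz
  band at rest; very low signal-to-noise recordings degrade to quality
  masking rather than graceful IBI estimation.
* Clock synchronization is affine only — two parameters, no drift
  beyond a constant rate — which matches crystal-clock behavior over a
  night but not thermal drift over weeks.
* Sleep-onset and latency definitions reference the recording start;
  lights-off annotations are not modeled.
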