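---
title: "Tracking steady-state evoked potential dynamics by column-wise averaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking steady-state evoked potential dynamics by column-wise averaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssepTrack)
```

## The problem

Steady-state evoked potentials — SSVEPs, ASSRs, SSSEPs — are EEG
oscillations phase-locked to a periodic sensory stimulus. The classical way
to pull them out of the background EEG is to average consecutive
stimulus-locked epochs *within* a recording. That estimator assumes the
response is stationary: a single stereotyped oscillation plus random noise.
Whenever the response itself evolves — integration at stimulus onset,
adaptation under sustained stimulation, extinction after offset — the
within-run ("sequential") average conflates all of those states into one
number and the dynamics are lost.

The alternative implemented here rests on one assumption: **the time
evolution of the response amplitude is the same across independent
stimulation runs** separated by sufficiently long rest pauses. Record the
same stimulation many times, cut every run into stimulus-locked epochs, and
arrange the epochs in a matrix with one row per run and one column per
epoch position. Averaging **down the columns** — across runs, never across
positions — cancels the background EEG exactly as ordinary averaging does,
while each column's average still reflects the instantaneous response at
that point of the stimulation interval.

## The estimator

Let \(x_{ij}(s)\) be sample \(s\) of the epoch at position \(j\) of run
\(i\), with per-epoch weights \(w_{ij}\) and a rejection mask. The
column-wise average is

\[
\bar{x}_j(s) \;=\; \frac{\sum_{i \le k,\; \mathrm{kept}} w_{ij}\, x_{ij}(s)}
                        {\sum_{i \le k,\; \mathrm{kept}} w_{ij}},
\qquad w_{ij} = \frac{1}{\widehat{\mathrm{Var}}(x_{ij})}.
\]

Weights are the reciprocal sample variance of each epoch, so epochs
inflated by motion or muscle activity contribute less. Normalising by the
sum of the weights keeps the average in volts; with equal variances the
weighted and unweighted averages coincide (this is tested to 1e-12).

From each averaged column three quantities are extracted:

* **response amplitude** — the single-sided FFT amplitude at the
  stimulation (modulation) frequency, with the FFT length equal to the
  epoch length and no windowing by default;
* **residual noise level (RNL)** — the root mean square of the bin
  amplitudes within ±3 Hz of the response frequency, excluding the
  response bin and one guard bin per side;
* **peak signal-to-noise ratio** —
  \(\mathrm{pSNR} = 10 \log_{10}(A^2 / \mathrm{RNL}^2)\) dB.

Plotting these against the column midpoint time gives the response time
course; plotting them against the number of averaged runs \(k\) gives the
progressive curves, which stabilise as \(\mathrm{RNL}(k) \propto
1/\sqrt{k}\) and \(\mathrm{pSNR}(k) - \mathrm{pSNR}(1) \approx
10\log_{10} k\) for independent background noise.

```{r example, eval = FALSE}
cfg <- ssep_sim_config(seed = 42)          # 30 runs x 40 s, 10 Hz, fs 512
fit <- ssep_track(simulate_dataset(cfg), epoch_length = 4)
summary(fit)
plot(fit)
```

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| epoch length | 4 | s | time resolution of the dynamics; must hold an integer number of response cycles so the response falls on an exact FFT bin (4 s × 10 Hz = 40 cycles, 0.25 Hz resolution) |
| number of runs | 30 | – | RNL and pSNR typically reach their asymptote after ~20 averaged runs; 30 is conservative |
| rest pause | 3 × stimulus length | s | makes consecutive runs statistically independent (`plan_session()`) |
| RNL band half-width | 3 | Hz | flanking band wide enough for a stable RMS (12 bins/side at 0.25 Hz) yet narrow enough to sample the noise floor local to the response |
| guard bins | 1 per side | bins | leakage protection around the response bin under floating point |
| rejection thresholds | off | V | gradient / peak-to-peak / absolute amplitude per epoch; typical values 50 / 100 / 100 µV |
| run-QC drop | 5% | – | strict inequality: a run at exactly 95% of the reference amplitude is kept |
| overlap | 0 | – | overlapping epochs refine the time axis; the default keeps columns independent |

Two conventions deserve a note. "Vector averaging" of noise bins is
implemented as the RMS of their amplitudes: the complex mean of
independent, random-phase bins converges to zero and cannot measure a
noise *level*; a complex-mean variant is available via
`compute_rnl(method = "complex")` for sensitivity checks. And rejected
epochs are *masked* (weight 0), never removed, because deleting epochs
before the matrix is assembled breaks the column alignment the whole
method depends on.

## The synthetic-data generator

Every stage is testable against simulated sessions with a known ground
truth. One run is

\[
y(t) = e(t)\,\sin(2\pi f t + \varphi_{\mathrm{run}}) + \text{pink} +
\text{white} + \text{artifacts},
\]

with the response envelope \(e(t)\) shared by all runs (the method's core
assumption) and the noise drawn independently per run. The default
envelope is a rise-times-adaptation product
\((1 - e^{-t/\tau_r})\,[A_p + (A_0 - A_p)e^{-\max(0, t - t_{peak})/\tau_a}]\)
with \(\tau_r = 4\) s, \(t_{peak} = 12\) s, \(\tau_a = 6\) s, peak 2 µV and
plateau 1.2 µV: a response that builds up over roughly the first 12 s,
adapts over the following stretch, and settles — the qualitative time
course reported for human SSVEPs under sustained 10 Hz photic stimulation.
Amplitudes in the low-microvolt range and a background of 4 µV white plus
8 µV pink (1/f) noise are typical of occipital scalp EEG. Phase is constant
within a run and jittered across runs with SD 0.1 rad, reflecting the
empirical finding that run-to-run phase varies far less than amplitude; the
residual attenuation of the across-run average, \(e^{-\sigma_\varphi^2/2}\),
is below 1% at that level.

Pink noise is synthesised by spectral shaping of Gaussian white noise
(bin gain \(f^{-\alpha/2}\)), which gives exact control of the spectral
slope. Blinks are positive raised-cosine transients (150 µV, 0.3 s) aimed
at the peak-to-peak and amplitude criteria; motion spikes are
single-sample transients (100 µV) aimed at the gradient criterion — a
transient rather than a sustained step, so one spike does not leak a
baseline shift into every later epoch of its run.

What the simulator does **not** emulate: volume conduction and scalp
topography (channels are i.i.d. copies), non-stationary noise, true ocular
artifact morphology, or run-to-run envelope variability. Passing tests on
simulated sessions therefore demonstrate the estimator's statistical
behaviour under its own assumptions, not robustness to every feature of
real EEG; the input contract assumes ocular artifacts have already been
removed upstream (e.g. by ICA), with only threshold rejection in scope
here.

## Numerical choices

* **Zero-phase filtering.** Band-pass (0.5–300 Hz default) and notch
  filters are forward–backward 4th/2nd-order Butterworth
  (`signal::filtfilt`), so epoch timing relative to the stimulus is never
  shifted. Filtering is applied to the continuous recording before
  segmentation.
* **Resampling** is Fourier-domain truncation at the new Nyquist
  frequency: exact for band-limited signals, inherently anti-aliased,
  zero-phase, and free of the edge transients a polyphase FIR resampler
  introduces on short records. It requires the rate ratio to map the
  record to an integer number of samples, which holds for the standard
  2048 → 512 Hz reduction.
* **Detrending** removes the per-channel least-squares intercept and
  slope. The discrete ramp is not exactly orthogonal to a sampled
  integer-cycle sinusoid, so detrending perturbs the waveform by a couple
  of percent in the time domain — but the amplitude at the response bin
  changes by well under 0.1%, which is what the estimator uses.
* **Exact-bin enforcement.** `epoch_length * stim_freq` must be an
  integer, validated at matrix build time and again at FFT time with a
  suggestion of the nearest valid epoch lengths. This removes any need
  for windowing (Hann is available, with its amplitude correction, for
  non-ideal cases).
* **Degenerate inputs.** A column whose epochs are all rejected is an
  error (its average would be undefined); a zero-variance epoch cannot be
  inverse-variance weighted and is reported by index; single-run sessions
  degrade to a k = 1 progressive point with a warning.
* **Reproducibility.** Run `i` of a dataset is generated under a seed
  derived from `(dataset seed, i)`, so datasets are bit-identical across
  calls and runs are independent but individually reproducible; the
  session RNG state is saved and restored.

## Design decisions that were genuinely open

* The envelope's functional form is not prescribed anywhere; the
  rise-times-adaptation product was chosen because it is the simplest
  smooth curve with the three observed regimes, and a piecewise-linear
  alternative is provided for exactly-known test cases.
* Rejection granularity is per (run, epoch, channel); an `"any"` mode
  extends a rejection across channels for single-channel analyses.
* Epoch weights use the variance of the preprocessed epoch as recorded,
  not of an artifact-masked version.
* The progressive curves recompute the average for every k rather than
  updating incrementally — quadratic in the number of runs, but clear,
  and a 30-run session still fits in well under a second.
* Progressive summaries (mean ± SD over the m columns) are computed per
  channel, never pooled across channels.
* The first column can carry a pre-stimulus baseline (kept separate from
  the analysis window) so onset dynamics can be displayed without
  contaminating the spectral estimates.

## Problem sizes used in the test suite

The bundled tests exercise the canonical 30-run × 40-s session at 512 Hz
for geometry and envelope recovery, and compact 8-run × 8-s sessions at
128 Hz (2-s epochs, 20 cycles each) for the Monte-Carlo suites: 100
replicates for the 1/√k noise law and the pSNR gain, 500 replicates for
the closed-form white-noise RNL check. These sizes give Monte-Carlo
standard errors comfortably below the asserted tolerances while keeping
the whole suite in seconds.

## Known limitations

* Amplitude attenuation from cross-run phase variability is not
  corrected, only kept small by assumption; strongly variable phase would
  bias all columns downward.
* The RNL band assumes the background is locally flat around the response
  frequency; a strong alpha peak adjacent to a 10 Hz SSVEP inflates the
  RNL (the band is configurable, and harmonics can be excluded by
  narrowing it).
* No statistical response-detection test (F-test, Hotelling's T²) is
  provided: the package estimates amplitudes and noise levels, it does
  not decide presence.
* EDF export quantises to 16 bits over the per-channel data range, which
  is ample for EEG but not lossless.
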