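# ssepTrack

Tracking the time evolution of steady-state evoked potentials by
column-wise averaging of repeated stimulation runs.

## The problem

Steady-state evoked potentials (SSVEP, ASSR, SSSEP) are EEG oscillations
phase-locked to a periodic sensory stimulus. The classical estimator —
averaging consecutive stimulus-locked epochs *within* a recording — assumes
a stationary response, so it cannot describe onset integration, adaptation
under sustained stimulation, or extinction after stimulus offset: averaging
across time blurs exactly the dynamics of interest.

`ssepTrack` implements the across-run alternative for experimenters who can
record the same stimulation many times. Runs are cut into stimulus-locked
epochs and arranged in an *n* × *m* data matrix (*n* runs, *m* epoch
positions). Epochs occupying the **same position** in different runs are
averaged — down the columns, never along the rows:

```
x̄_j(s) = Σ_i w_ij · x_ij(s) / Σ_i w_ij ,   w_ij = 1 / Var(x_ij)
```

over the non-rejected epochs of the first *k* runs. Background EEG cancels
as in ordinary averaging, but each column's average still reflects the
*instantaneous* response at that point of the stimulation interval. From
every averaged column the package extracts

* the **response amplitude** — single-sided FFT amplitude at the
  stimulation (modulation) frequency, FFT length = epoch length;
* the **residual noise level (RNL)** — RMS of the FFT bin amplitudes
  within ±3 Hz of the response, excluding the response bin and one guard
  bin per side;
* the **peak SNR** — `pSNR = 10·log10(amplitude² / RNL²)` in dB;

as functions of time (the evolution curve) and of the number of averaged
runs (the progressive curves, which follow `RNL(k) ∝ 1/√k` and
`pSNR gain ≈ 10·log10 k` for independent noise).

The package also provides a synthetic multi-run EEG generator with a known
time-varying response envelope (for validation and power analysis),
zero-phase preprocessing (band-pass, notch, Fourier resampling,
segmentation, detrending, baseline correction), threshold-based epoch
rejection with inverse-variance weighting, run-level amplitude QC, a
session-planning helper (rest pauses ≥ 3× the stimulus length), and EDF /
delimited-text readers and writers.

## Worked example

Simulate the canonical session — 30 runs of 40-s stimulation modulated at
10 Hz, sampled at 512 Hz, with a response that builds up over ~12 s, adapts
and settles (peak 2 µV against a 4 µV white + 8 µV pink background) — then
fit the time course with 4-s epochs:

```r
library(ssepTrack)
cfg <- ssep_sim_config(seed = 42)
fit <- ssep_track(simulate_dataset(cfg), epoch_length = 4)
summary(fit)
#> Column-wise averaged steady-state response: 30 runs x 10 columns, 0 epoch(s) rejected
#>   amplitude peaks at column 3 (t = 10.0 s): 1.83 uV
#>   mean RNL 0.120 uV; mean pSNR 21.0 dB
#>  column time_s channel amplitude_uV rnl_uV psnr_dB
#>       1      2     ch1        0.807  0.114   17.01
#>       2      6     ch1        1.563  0.120   22.32
#>       3     10     ch1        1.829  0.129   23.02
#>       4     14     ch1        1.749  0.134   22.31
#>       5     18     ch1        1.569  0.126   21.89
#>       6     22     ch1        1.393  0.124   21.02
#>       7     26     ch1        1.171  0.087   22.54
#>       8     30     ch1        1.187  0.113   20.39
#>       9     34     ch1        1.276  0.131   19.75
#>      10     38     ch1        1.169  0.118   19.93
```

The amplitude column tracks the simulated envelope: low in the first 4-s
epoch while the response builds up, maximal in column 3 (around 12 s after
onset), then declining toward the adapted plateau — dynamics a within-run
average would have flattened into a single number. The RNL stays flat
across columns (stable recording conditions), so the pSNR follows the
amplitude. `coef(fit)` returns the per-column amplitudes, `plot(fit)` draws
the evolution and progressive panels, and `as.data.frame(fit)` exports the
table.

The progressive curves show why 30 runs suffice:

```r
fit$progressive[c(1, 5, 10, 20, 30), c("k", "rnl_mean", "psnr_mean")]
#>     k rnl_uV psnr_dB
#> 1   1  0.605   5.809
#> 5   5  0.277  14.040
#> 10 10  0.207  16.303
#> 20 20  0.141  19.550
#> 30 30  0.120  21.020
```

the RNL falls as 1/√k and has essentially reached its asymptote by ~20
runs. Session planning applies the 3× pause rule:

```r
plan_session(40)
#> 40 s stimulation x factor 3 -> pause 120 s (2 min)
```

A thin command-line front end (`inst/scripts/ssep-track`) exposes
`simulate`, `analyze`, `run` and `plan-session` subcommands over the same
functions, and `run_pipeline()` executes the whole chain from a YAML or
list configuration, writing delimited-text reports and a reproducibility
log.

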