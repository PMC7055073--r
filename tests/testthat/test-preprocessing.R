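# Filtering, resampling, segmentation, detrending, baseline correction.

test_that("band-pass keeps the response band and removes drift and DC", {
  rec <- sine_recording(freq = 10, amp = 1e-6, fs = 2048, pre = 0, dur = 10,
                        post = 0)
  out <- bandpass(rec, 0.5, 300)
  mid <- 5000:15000
  expect_equal(max(abs(out$data[mid, 1])), 1e-6, tolerance = 0.01)

  t <- (seq_len(10 * 2048) - 1) / 2048
  drift <- ssep_recording(sin(2 * pi * 0.05 * t), fs = 2048, stim_onset = 0,
                          stim_duration = 10, stim_freq = 10)
  outd <- bandpass(drift, 0.5, 300)
  expect_lt(max(abs(outd$data[mid, 1])), 0.1)

  # DC offset: gone once the high-pass edge transient has decayed
  dc <- ssep_recording(rep(1, 10 * 2048), fs = 2048, stim_onset = 0,
                       stim_duration = 10, stim_freq = 10)
  expect_lt(max(abs(bandpass(dc, 0.5, 300)$data[mid, 1])), 0.02)
})

test_that("band edges outside Nyquist are rejected", {
  rec <- sine_recording(fs = 512)
  expect_error(bandpass(rec, 0.5, 300), "fs/2")
  expect_error(bandpass(rec, 0, 100), "fs/2")
})

test_that("notch suppresses mains but not the response", {
  fs <- 512
  t <- (seq_len(4 * fs) - 1) / fs
  mk <- function(f) ssep_recording(sin(2 * pi * f * t), fs = fs,
                                   stim_onset = 0, stim_duration = 4,
                                   stim_freq = 10)
  mid <- 800:1200
  out50 <- notch(mk(50), 50)
  expect_lt(max(abs(out50$data[mid, 1])), 0.03)
  out10 <- notch(mk(10), 50)
  expect_equal(max(abs(out10$data[mid, 1])), 1, tolerance = 0.01)
  expect_warning(notch(mk(10), 10), "within 2 Hz")
})

test_that("filters are zero-phase", {
  fs <- 512
  t <- (seq_len(8 * fs) - 1) / fs
  rec <- ssep_recording(sin(2 * pi * 10 * t), fs = fs, stim_onset = 0,
                        stim_duration = 8, stim_freq = 10)
  out <- bandpass(rec, 0.5, 100)
  mid <- 1025:3072
  cc <- stats::ccf(rec$data[mid, 1], out$data[mid, 1], lag.max = 10,
                   plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("resampling preserves amplitude, timing metadata, and guards Nyquist", {
  rec <- sine_recording(freq = 10, amp = 1e-6, fs = 2048, pre = 1, dur = 8,
                        post = 1)
  out <- resample(rec, 512)
  expect_equal(out$fs, 512)
  expect_equal(nrow(out$data), nrow(rec$data) / 4)
  expect_equal(out$stim_onset, 1)
  mid <- 1000:3000
  expect_equal(max(abs(out$data[mid, 1])), 1e-6, tolerance = 0.01)
  expect_error(resample(rec, 15), "Nyquist")
  expect_identical(resample(rec, 2048), rec)
})

test_that("segmentation counts epochs correctly, with and without overlap", {
  rec <- sine_recording(freq = 10, fs = 128, pre = 1, dur = 40, post = 1)
  expect_length(segment(rec, 4)$epochs, 10)
  expect_length(segment(rec, 4, overlap = 0.5)$epochs, 19)
  expect_error(segment(sine_recording(dur = 3), 4), "exceeds")
})

test_that("segmented epochs concatenate back to the analysis window", {
  rec <- sine_recording(freq = 10, fs = 128, pre = 1, dur = 8, post = 1)
  seg <- segment(rec, 2)
  joined <- do.call(rbind, seg$epochs)
  onset <- round(rec$stim_onset * rec$fs)
  expect_identical(joined, rec$data[(onset + 1):(onset + nrow(joined)), ,
                                    drop = FALSE])
})

test_that("pre-stimulus baseline is extracted separately", {
  rec <- sine_recording(freq = 10, fs = 128, pre = 1, dur = 8, post = 1)
  seg <- segment(rec, 2, include_pre_stim = 0.5)
  expect_equal(nrow(seg$baseline), 64)
  expect_true(all(seg$baseline == 0))              # pre-stim is silent here
  expect_equal(nrow(seg$epochs[[1]]), 256)         # analysis window unchanged
  expect_error(segment(rec, 2, include_pre_stim = 2), "pre-stimulus")
})

test_that("dc_detrend removes ramps exactly and zeroes mean and slope", {
  n <- 512
  ramp <- seq(0, 1, length.out = n)
  expect_lt(max(abs(dc_detrend(ramp))), 1e-9)
  out <- dc_detrend(5 + 3 * ramp + rnorm(n))
  tc <- seq_len(n) - (n + 1) / 2
  expect_equal(mean(out), 0, tolerance = 1e-12)
  expect_equal(sum(tc * out) / sum(tc^2), 0, tolerance = 1e-12)
  expect_identical(dc_detrend(numeric(n)), numeric(n))
})

test_that("dc_detrend barely perturbs an integer-cycle response", {
  # discrete least-squares detrending projects a small ramp component out of
  # a sampled sinusoid (a few percent in the time domain), but the amplitude
  # at the response bin is preserved to well under 0.1%
  n <- 2048; fs <- 512
  s <- sin(2 * pi * 10 * ((seq_len(n) - 1) / fs))
  d <- dc_detrend(s)
  a0 <- fft_amplitude(s, fs, 10)$amplitude
  a1 <- fft_amplitude(d, fs, 10)$amplitude
  expect_equal(a1, a0, tolerance = 1e-3)
  expect_lt(max(abs(d - s)), 0.03)
})

test_that("baseline correction subtracts the right per-channel scalar", {
  ep <- cbind(rep(5e-6, 100), rep(-2e-6, 100))
  bl <- cbind(rep(5e-6, 30), rep(-2e-6, 30))
  out <- baseline_correct(ep, baseline = bl, fs = 100)
  expect_true(all(out == 0))
  # fallback: whole-epoch mean
  out2 <- baseline_correct(ep)
  expect_true(all(out2 == 0))
  # zero-mean baseline leaves a sinusoid unchanged
  s <- sin(2 * pi * seq_len(100) / 10)
  expect_equal(baseline_correct(s, baseline = c(1e-9, -1e-9)), s,
               tolerance = 1e-12)
  expect_error(baseline_correct(ep, baseline = bl[1:10, ], fs = 100),
               "at least")
})

test_that("re-referencing subtracts the common average or a channel subset", {
  data <- cbind(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  rec <- ssep_recording(data, fs = 50, stim_onset = 0, stim_duration = 1,
                        stim_freq = 5)
  avg <- rereference(rec)
  expect_equal(rowMeans(avg$data), rep(0, 50), tolerance = 1e-12)
  sub <- rereference(rec, c("a", "b"))
  expect_equal(sub$data[, "c"], data[, "c"] - rowMeans(data[, c("a", "b")]))
  expect_error(rereference(rec, "zz"), "unknown reference")
})
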