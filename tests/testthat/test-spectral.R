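# FFT amplitude, residual noise level, peak SNR.

test_that("an exact-bin sinusoid of amplitude A reads A at its bin", {
  fs <- 512; t <- (seq_len(4 * fs) - 1) / fs
  fa <- fft_amplitude(1e-6 * sin(2 * pi * 10 * t), fs, 10)
  expect_equal(fa$amplitude, 1e-6, tolerance = 1e-9)
  expect_equal(fa$bin, 41L)                 # 0.25 Hz resolution
  expect_equal(fa$spectrum$freq[fa$bin], 10)
  expect_equal(fft_amplitude(numeric(2048), fs, 10)$amplitude, 0)
})

test_that("orthogonal tones do not leak into each other's bins", {
  fs <- 512; t <- (seq_len(4 * fs) - 1) / fs
  x <- 1e-6 * sin(2 * pi * 10 * t) + 1e-6 * sin(2 * pi * 17 * t)
  # independent oracle: direct DFT projection onto the 10 Hz bin
  n <- length(x)
  proj <- 2 / n * abs(sum(x * exp(-2i * pi * 40 * (seq_len(n) - 1) / n)))
  expect_equal(proj, 1e-6, tolerance = 1e-9)
  expect_equal(fft_amplitude(x, fs, 10)$amplitude, proj, tolerance = 1e-12)
  expect_equal(fft_amplitude(x, fs, 17)$amplitude, 1e-6, tolerance = 1e-9)
})

test_that("amplitude is invariant to the sinusoid's phase", {
  fs <- 256; t <- (seq_len(2 * fs) - 1) / fs
  amps <- vapply(c(0, 0.7, 1.9, pi), function(ph) {
    fft_amplitude(1e-6 * sin(2 * pi * 10 * t + ph), fs, 10)$amplitude
  }, numeric(1))
  expect_equal(amps, rep(1e-6, 4), tolerance = 1e-9)
})

test_that("non-integer cycle counts are rejected with suggested lengths", {
  fs <- 512; x <- rnorm(fs * 4.1)
  expect_error(fft_amplitude(x, fs, 10), "integer number")
  expect_error(fft_amplitude(x, fs, 10), "4.1")
})

test_that("Parseval consistency of the single-sided scaling", {
  # for a zero-mean epoch: sum of squared single-sided amplitudes equals
  # (2/N) * sum(x^2), up to the halved Nyquist-bin contribution
  set.seed(3)
  x <- rnorm(512); x <- x - mean(x)
  sp <- amplitude_spectrum(x, 512)
  n <- length(x)
  nyq <- abs(stats::fft(x)[n / 2 + 1] * 2 / n)^2 / 2
  expect_equal(sum(sp$amplitude^2) + nyq, 2 / n * sum(x^2),
               tolerance = 1e-9)
})

test_that("RNL is the RMS of the flanking bin amplitudes", {
  # constant noise bins -> RNL equals the constant
  spec <- data.frame(freq = seq(0, 40, by = 0.25))
  spec$amplitude <- 2e-6
  spec$coef <- complex(modulus = spec$amplitude, argument = 0)
  expect_equal(compute_rnl(spec, 10), 2e-6)
  spec$amplitude <- 0; spec$coef <- 0 + 0i
  expect_equal(compute_rnl(spec, 10), 0)
})

test_that("RNL excludes the response bin and its guard bins", {
  fs <- 512; t <- (seq_len(4 * fs) - 1) / fs
  x <- 5e-6 * sin(2 * pi * 10 * t)                # huge response, no noise
  sp <- amplitude_spectrum(x, fs)
  expect_lt(compute_rnl(sp, 10), 1e-12)
})

test_that("RNL depends on bin amplitudes only, not phases", {
  spec <- data.frame(freq = seq(0, 40, by = 0.5))
  set.seed(9)
  spec$amplitude <- runif(nrow(spec), 0, 1e-6)
  spec$coef <- complex(modulus = spec$amplitude,
                       argument = runif(nrow(spec), -pi, pi))
  r1 <- compute_rnl(spec, 10)
  spec$coef <- complex(modulus = spec$amplitude, argument = 0)
  expect_identical(compute_rnl(spec, 10), r1)
})

test_that("white-noise RNL matches the closed-form expected bin amplitude", {
  # E[RNL] for white noise of sd sigma over an N-sample epoch is
  # 2*sigma/sqrt(N) with the single-sided 2/N scaling
  fs <- 512; n <- 4 * fs; sigma <- 1
  set.seed(101)
  rnls <- replicate(500, {
    sp <- amplitude_spectrum(rnorm(n, sd = sigma), fs)
    compute_rnl(sp, 10)
  })
  expect_equal(mean(rnls), 2 * sigma / sqrt(n), tolerance = 0.05)
})

test_that("too-narrow noise bands and DC-reaching bands are errors", {
  sp <- amplitude_spectrum(rnorm(512), 128)
  expect_error(compute_rnl(sp, 10, band_halfwidth = 0.5), "noise bins")
  expect_error(compute_rnl(sp, 2, band_halfwidth = 3), "DC")
})

test_that("pSNR follows its definition and antisymmetry", {
  expect_equal(compute_psnr(10, 1), 20)
  expect_equal(compute_psnr(1, 1), 0)
  expect_equal(compute_psnr(1, 2), 10 * log10(0.25), tolerance = 1e-9)
  a <- 3.7e-6; r <- 0.9e-6
  expect_equal(compute_psnr(a, r) + compute_psnr(r, a), 0, tolerance = 1e-12)
  expect_warning(p0 <- compute_psnr(1, 0), "infinite")
  expect_identical(p0, Inf)
})

test_that("the Hann window preserves an exact-bin amplitude after correction", {
  fs <- 256; t <- (seq_len(2 * fs) - 1) / fs
  fa <- fft_amplitude(1e-6 * sin(2 * pi * 10 * t), fs, 10, window = "hann")
  expect_equal(fa$amplitude, 1e-6, tolerance = 0.01)
})

test_that("evolution assembles per-column estimates with midpoint times", {
  cfg <- clean_config(amplitude = 1e-6, n_runs = 2)
  mat <- epoch_matrix_from_dataset(simulate_dataset(cfg), epoch_length = 2)
  avg <- columnwise_average(mat)
  ev <- suppressWarnings(evolution(avg))
  expect_equal(nrow(ev), 4)
  expect_equal(ev$time, c(1, 3, 5, 7))
  expect_equal(ev$amplitude, rep(1e-6, 4), tolerance = 1e-6)
  expect_true(all(ev$rnl < 1e-12))
})

test_that("in noise-only data the response bin behaves like a noise bin", {
  cfg <- small_config(n_runs = 2, seed = 77, envelope = no_signal(),
                      noise = noise_params(white_sd = 5e-6, pink_sd = 0))
  res <- lapply(1:30, function(i) {
    cfg$seed <- 1000 + i
    mat <- epoch_matrix_from_dataset(simulate_dataset(cfg), epoch_length = 2)
    ev <- evolution(columnwise_average(mat, use_weights = FALSE))
    ev[, c("amplitude", "rnl")]
  })
  res <- do.call(rbind, res)
  # the mean squared "response" amplitude matches the mean squared RNL
  ratio_db <- 10 * log10(mean(res$amplitude^2) / mean(res$rnl^2))
  expect_lt(abs(ratio_db), 3)
})
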