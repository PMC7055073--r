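# Column-wise weighted averaging, sequential averaging, progressive curves.

test_that("averaging identical runs reproduces any single run sample-exactly", {
  cfg <- clean_config(amplitude = 1e-6, n_runs = 4)
  mat <- epoch_matrix_from_dataset(simulate_dataset(cfg), epoch_length = 2)
  for (k in c(1, 2, 4)) {
    avg <- columnwise_average(mat, k = k, use_weights = FALSE)
    expect_equal(avg$data[2, 1, ], mat$epochs[1, 2, 1, ], tolerance = 1e-14)
  }
})

test_that("unit-weight averaging is the arithmetic mean across runs", {
  m <- structure(
    list(epochs = array(0, dim = c(2, 1, 1, 8)), baseline = NULL,
         weights = array(1, dim = c(2, 1, 1)),
         rejected = array(FALSE, dim = c(2, 1, 1)),
         fs = 4, epoch_length = 2, stim_freq = 1, overlap = 0,
         run_ids = c("a", "b"), channel_labels = "ch1"),
    class = "ssep_epoch_matrix")
  m$epochs[1, 1, 1, ] <- 1e-6
  m$epochs[2, 1, 1, ] <- 3e-6
  avg <- columnwise_average(m)
  expect_equal(avg$data[1, 1, ], rep(2e-6, 8))
  # inverse-variance weights 1 and 0.25 on constants 0 and 5 uV -> 1 uV
  m$epochs[1, 1, 1, ] <- 0
  m$epochs[2, 1, 1, ] <- 5e-6
  m$weights[, 1, 1] <- c(1, 0.25)
  expect_equal(columnwise_average(m)$data[1, 1, ], rep(1e-6, 8))
})

test_that("equal variances make weighted and unweighted averages coincide", {
  cfg <- small_config(n_runs = 5, seed = 23)
  mat <- epoch_matrix_from_dataset(simulate_dataset(cfg), epoch_length = 2)
  matw <- mat
  matw$weights[] <- 0.37          # equal weights, arbitrary scale
  aw <- columnwise_average(matw, use_weights = TRUE)
  au <- columnwise_average(mat, use_weights = FALSE)
  expect_equal(aw$data, au$data, tolerance = 1e-12)
})

test_that("averaging is linear in the data for fixed weights and masks", {
  cfg <- small_config(n_runs = 3, seed = 41)
  m1 <- epoch_matrix_from_dataset(simulate_dataset(cfg), epoch_length = 2)
  cfg$seed <- 42
  m2 <- epoch_matrix_from_dataset(simulate_dataset(cfg), epoch_length = 2)
  m12 <- m1
  m12$epochs <- 2 * m1$epochs + 3 * m2$epochs
  lhs <- columnwise_average(m12)$data
  rhs <- 2 * columnwise_average(m1)$data + 3 * columnwise_average(m2)$data
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("the full average is invariant to run order", {
  cfg <- small_config(n_runs = 6, seed = 57)
  mat <- epoch_matrix_from_dataset(simulate_dataset(cfg), epoch_length = 2)
  mat <- compute_weights(mat)
  perm <- c(4, 1, 6, 2, 5, 3)
  shuf <- mat
  shuf$epochs <- mat$epochs[perm, , , , drop = FALSE]
  shuf$weights <- mat$weights[perm, , , drop = FALSE]
  shuf$rejected <- mat$rejected[perm, , , drop = FALSE]
  expect_equal(columnwise_average(shuf)$data, columnwise_average(mat)$data,
               tolerance = 1e-12)
})

test_that("rejected epochs are excluded from their column's average", {
  cfg <- small_config(n_runs = 3, seed = 19)
  mat <- epoch_matrix_from_dataset(simulate_dataset(cfg), epoch_length = 2)
  mat$rejected[2, 1, 1] <- TRUE
  mat$weights[2, 1, 1] <- 0
  avg <- columnwise_average(mat, use_weights = FALSE)
  manual <- colMeans(rbind(mat$epochs[1, 1, 1, ], mat$epochs[3, 1, 1, ]))
  expect_equal(avg$data[1, 1, ], manual, tolerance = 1e-14)
  expect_equal(avg$effective_n[1, 1], 2)
  expect_equal(avg$effective_n[2, 1], 3)
  # a column with no contributors among the first k runs errors
  mat$rejected[1, 1, 1] <- TRUE; mat$weights[1, 1, 1] <- 0
  expect_error(columnwise_average(mat, k = 2), "no non-rejected")
})

test_that("sequential average matches column-wise only for constant envelopes", {
  # constant envelope: both estimate the same amplitude
  cfgc <- clean_config(amplitude = 1e-6, n_runs = 2)
  matc <- epoch_matrix_from_dataset(simulate_dataset(cfgc), epoch_length = 2)
  seq_amp <- fft_amplitude(sequential_average(matc, 1)[1, ], 128, 10)$amplitude
  ev <- suppressWarnings(evolution(columnwise_average(matc, use_weights = FALSE)))
  expect_equal(seq_amp, ev$amplitude[1], tolerance = 1e-6)

  # linearly decaying envelope 1 -> 0: the within-run average halves the
  # amplitude while column 1 still sees ~95% of it
  cfgd <- small_config(
    n_runs = 2, stim_duration = 40, fs = 128, seed = 1,
    noise = noise_params(white_sd = 0, pink_sd = 0),
    envelope = envelope_piecewise(c(0, 40), c(1e-6, 0))
  )
  matd <- epoch_matrix_from_dataset(simulate_dataset(cfgd), epoch_length = 4)
  seq_amp <- fft_amplitude(sequential_average(matd, 1)[1, ], 128, 10)$amplitude
  col1 <- suppressWarnings(
    evolution(columnwise_average(matd, use_weights = FALSE)))$amplitude[1]
  expect_equal(seq_amp, 0.5e-6, tolerance = 0.02)
  expect_equal(col1, 0.95e-6, tolerance = 0.02)
  expect_gt(col1 / seq_amp, 1.5)
})

test_that("m = 1 sequential average is the identity", {
  rec <- sine_recording(freq = 10, fs = 128, pre = 0, dur = 2, post = 0)
  mat <- build_epoch_matrix(list(segment(rec, 2)))
  expect_equal(sequential_average(mat, 1)[1, ], mat$epochs[1, 1, 1, ])
})

test_that("progressive curves are flat for a zero-noise constant envelope", {
  cfg <- clean_config(amplitude = 1e-6, n_runs = 4)
  mat <- epoch_matrix_from_dataset(simulate_dataset(cfg), epoch_length = 2)
  pg <- suppressWarnings(progressive_curves(mat, use_weights = FALSE))
  expect_equal(pg$k, 1:4)
  expect_equal(pg$amplitude_mean, rep(1e-6, 4), tolerance = 1e-6)
  expect_equal(pg$amplitude_sd, rep(0, 4), tolerance = 1e-12)
})

test_that("shuffled progressive order keeps the k = n point unchanged", {
  cfg <- small_config(n_runs = 5, seed = 71)
  mat <- epoch_matrix_from_dataset(simulate_dataset(cfg), epoch_length = 2)
  p1 <- progressive_curves(mat, use_weights = FALSE)
  p2 <- progressive_curves(mat, order = "shuffled", shuffle_seed = 3,
                           use_weights = FALSE)
  expect_equal(p1$amplitude_mean[5], p2$amplitude_mean[5], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(p1$amplitude_mean[1], p2$amplitude_mean[1])))
})
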