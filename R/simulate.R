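#' Simulation configuration for multi-run steady-state EEG
#'
#' Describes a full synthetic experiment: repeated stimulation runs with an
#' embedded steady-state response of known, time-varying amplitude on top of
#' pink/white background noise and optional blink/motion artifacts. The
#' defaults reproduce the canonical session design for tracking SSVEP
#' dynamics: 30 runs of 40 s of stimulation, sinusoidal 10 Hz amplitude
#' modulation, recorded at 512 Hz, later segmented into 4-s epochs (a
#' 30 x 10 data matrix).
#'
#' Within a run the response phase is constant; across runs it is jittered
#' by a zero-mean Gaussian draw with standard deviation `phase_jitter_sd`
#' (empirically the run-to-run phase of steady-state responses varies much
#' less than their amplitude, which is what makes across-run averaging
#' viable).
#'
#' @param n_runs Number of experimental runs (>= 1).
#' @param stim_duration Stimulation length per run, seconds.
#' @param pre_stim Pre-stimulus interval recorded before onset, seconds.
#' @param post_stim Post-stimulus interval recorded after offset, seconds.
#' @param fs Sampling rate, Hz; must exceed `2 * stim_freq`.
#' @param stim_freq Stimulation (modulation) frequency, Hz.
#' @param phase_jitter_sd Run-to-run phase jitter standard deviation, radians.
#' @param envelope Response envelope, see [envelope_params()].
#' @param noise Background noise, see [noise_params()].
#' @param artifacts Artifact model, see [artifact_params()].
#' @param n_channels Number of (i.i.d.) channels.
#' @param seed Integer seed controlling the whole dataset.
#' @return An object of class `ssep_sim_config`.
#' @seealso [simulate_run()], [simulate_dataset()]
#' @export
ssep_sim_config <- function(n_runs = 30,
                            stim_duration = 40,
                            pre_stim = 1,
                            post_stim = 1,
                            fs = 512,
                            stim_freq = 10,
                            phase_jitter_sd = 0.1,
                            envelope = envelope_params(),
                            noise = noise_params(),
                            artifacts = artifact_params(),
                            n_channels = 1,
                            seed = 1L) {
  stopifnot(
    is_scalar_number(n_runs), n_runs >= 1,
    is_scalar_number(stim_duration), stim_duration > 0,
    is_scalar_number(pre_stim), pre_stim >= 0,
    is_scalar_number(post_stim), post_stim >= 0,
    is_scalar_number(fs), is_scalar_number(stim_freq),
    fs > 2 * stim_freq,
    is_scalar_number(phase_jitter_sd), phase_jitter_sd >= 0,
    is_scalar_number(n_channels), n_channels >= 1,
    inherits(envelope, c("ssep_envelope", "ssep_envelope_pw")),
    inherits(noise, "ssep_noise"),
    inherits(artifacts, "ssep_artifacts")
  )
  structure(
    list(
      n_runs = as.integer(n_runs), stim_duration = stim_duration,
      pre_stim = pre_stim, post_stim = post_stim, fs = fs,
      stim_freq = stim_freq, phase_jitter_sd = phase_jitter_sd,
      envelope = envelope, noise = noise, artifacts = artifacts,
      n_channels = as.integer(n_channels), seed = as.integer(seed)
    ),
    class = "ssep_sim_config"
  )
}

#' @export
print.ssep_sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<ssep_sim_config> %d run(s): %g s pre + %g s stim @ %g Hz ",
           "modulation + %g s post, fs %g Hz, %d channel(s), seed %d\n"),
    x$n_runs, x$pre_stim, x$stim_duration, x$stim_freq, x$post_stim,
    x$fs, x$n_channels, x$seed
  ))
  invisible(x)
}

#' Simulate one experimental run
#'
#' Generates one recording: the envelope-modulated sinusoidal response during
#' the stimulation window (zero outside it), plus background noise and
#' artifacts everywhere. The run is fully reproducible given the dataset
#' seed and the run index; different run indices give statistically
#' independent noise but the identical response envelope — the core
#' assumption behind column-wise averaging.
#'
#' @param config An [ssep_sim_config()].
#' @param run_index Run number in `1:n_runs`.
#' @return An [ssep_recording()].
#' @export
simulate_run <- function(config, run_index) {
  stopifnot(inherits(config, "ssep_sim_config"),
            run_index >= 1, run_index <= config$n_runs)
  fs <- config$fs
  n_pre <- round(config$pre_stim * fs)
  n_stim <- round(config$stim_duration * fs)
  n_post <- round(config$post_stim * fs)
  n <- n_pre + n_stim + n_post

  with_local_seed(derive_seed(config$seed, run_index), {
    phase <- if (config$phase_jitter_sd > 0) {
      stats::rnorm(1, 0, config$phase_jitter_sd)
    } else 0
    # time from stimulus onset for the stim + post window
    t_rel <- (seq_len(n_stim + n_post) - 1) / fs
    env <- envelope_value(config$envelope, t_rel, config$stim_duration)
    resp <- numeric(n)
    resp[(n_pre + 1):n] <- env * sin(2 * pi * config$stim_freq * t_rel + phase)
    # extinction matters only within ~offset_tau; the envelope already
    # handles it, so the sinusoid continues into the post window
    data <- matrix(0, n, config$n_channels)
    for (ch in seq_len(config$n_channels)) {
      x <- resp + channel_noise(n, fs, config$noise)
      x <- add_artifacts(x, fs, config$artifacts)
      data[, ch] <- x
    }
    ssep_recording(
      data, fs = fs, stim_onset = config$pre_stim,
      stim_duration = config$stim_duration, stim_freq = config$stim_freq,
      run_id = sprintf("run%02d", run_index)
    )
  })
}

#' Simulate a complete multi-run dataset
#'
#' @param config An [ssep_sim_config()].
#' @return A list of [ssep_recording()] objects of length `n_runs`, of class
#'   `ssep_dataset`, with the ground-truth envelope attached as attribute
#'   `"envelope_truth"` (a data frame of time from stimulus onset and
#'   amplitude in volts, sampled at `fs`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "ssep_sim_config"))
  runs <- lapply(seq_len(config$n_runs), function(i) simulate_run(config, i))
  t_rel <- seq(0, config$stim_duration + config$post_stim, by = 1 / config$fs)
  truth <- data.frame(
    time = t_rel,
    amplitude = envelope_value(config$envelope, t_rel, config$stim_duration)
  )
  structure(runs, class = "ssep_dataset",
            envelope_truth = truth, config = config)
}

#' @export
print.ssep_dataset <- function(x, ...) {
  cat(sprintf("<ssep_dataset> %d run(s)\n", length(x)))
  if (length(x)) print(x[[1]])
  invisible(x)
}

#' Simulate method for simulation configurations
#'
#' `simulate(config)` is equivalent to [simulate_dataset()]; `nsim` overrides
#' the number of runs and `seed` the dataset seed.
#'
#' @param object An [ssep_sim_config()].
#' @param nsim Number of runs (defaults to `object$n_runs`).
#' @param seed Optional seed overriding `object$seed`.
#' @param ... Unused.
#' @return An `ssep_dataset` (list of recordings).
#' @export
simulate.ssep_sim_config <- function(object, nsim = object$n_runs,
                                     seed = NULL, ...) {
  object$n_runs <- as.integer(nsim)
  if (!is.null(seed)) object$seed <- as.integer(seed)
  simulate_dataset(object)
}
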