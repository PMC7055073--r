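#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth band-pass, applied per channel.
#' Zero-phase filtering is used throughout so that epoch timing relative to
#' the stimulus is never shifted.
#'
#' @param rec An [ssep_recording()].
#' @param low,high Band edges in Hz, `0 < low < high < fs/2`.
#' @param order Butterworth order per pass (default 4).
#' @return The filtered recording (metadata unchanged).
#' @export
bandpass <- function(rec, low = 0.5, high = 300, order = 4) {
  stopifnot(inherits(rec, "ssep_recording"))
  if (!(low > 0 && low < high && high < rec$fs / 2)) {
    stop(sprintf("band [%g, %g] Hz must satisfy 0 < low < high < fs/2 = %g",
                 low, high, rec$fs / 2), call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) / (rec$fs / 2), type = "pass")
  update_data(rec, apply(rec$data, 2, function(x) signal::filtfilt(bf, x)))
}

#' Zero-phase notch (band-stop) filter
#'
#' Narrowband attenuation at the mains frequency (50 or 60 Hz). A warning is
#' emitted when the notch lies within 2 Hz of the stimulation frequency,
#' since it would then eat the response itself.
#'
#' @param rec An [ssep_recording()].
#' @param freq Notch centre frequency, Hz.
#' @param halfwidth Half-width of the stop band, Hz (default 1).
#' @param order Butterworth order per pass (default 2).
#' @return The filtered recording.
#' @export
notch <- function(rec, freq = 50, halfwidth = 1, order = 2) {
  stopifnot(inherits(rec, "ssep_recording"))
  if (!(freq > 0 && freq < rec$fs / 2)) {
    stop("notch frequency must lie in (0, fs/2)", call. = FALSE)
  }
  if (abs(freq - rec$stim_freq) <= 2) {
    warning(sprintf(
      "notch at %g Hz is within 2 Hz of the stimulation frequency (%g Hz)",
      freq, rec$stim_freq), call. = FALSE)
  }
  bs <- signal::butter(order, c(freq - halfwidth, freq + halfwidth) / (rec$fs / 2),
                       type = "stop")
  update_data(rec, apply(rec$data, 2, function(x) signal::filtfilt(bs, x)))
}

#' Anti-aliased resampling
#'
#' Resamples by Fourier-domain truncation: the spectrum is cut at the new
#' Nyquist frequency and inverse-transformed at the new length. This is
#' exact for band-limited signals, inherently anti-aliased, and zero-phase.
#' Stimulus onset and duration are preserved in seconds.
#'
#' @param rec An [ssep_recording()].
#' @param fs_new Target sampling rate, Hz; `fs_new <= fs` and
#'   `fs_new > 2 * stim_freq`.
#' @return The resampled recording.
#' @export
resample <- function(rec, fs_new = 512) {
  stopifnot(inherits(rec, "ssep_recording"))
  if (fs_new <= 2 * rec$stim_freq) {
    stop(sprintf(
      "fs_new = %g Hz violates the Nyquist condition for a %g Hz response",
      fs_new, rec$stim_freq), call. = FALSE)
  }
  if (fs_new > rec$fs) stop("upsampling is not supported", call. = FALSE)
  if (fs_new == rec$fs) return(rec)
  n <- nrow(rec$data)
  n_new_exact <- n * fs_new / rec$fs
  n_new <- round(n_new_exact)
  if (abs(n_new_exact - n_new) > 1e-6) {
    stop("fs_new/fs must map the record to an integer number of samples",
         call. = FALSE)
  }
  half <- floor(n_new / 2)
  resamp1 <- function(x) {
    X <- stats::fft(x)
    Y <- complex(n_new)
    Y[1] <- X[1]
    idx <- seq_len(half - 1)
    Y[1 + idx] <- X[1 + idx]
    Y[n_new + 1 - idx] <- X[n + 1 - idx]
    if (n_new %% 2 == 0) Y[half + 1] <- Re(X[half + 1])
    Re(stats::fft(Y, inverse = TRUE)) / n
  }
  out <- update_data(rec, apply(rec$data, 2, resamp1))
  out$fs <- fs_new
  out
}

#' Optional re-referencing
#'
#' Subtracts a reference signal from every channel: either the mean of a
#' named channel subset or the grand average of all channels. By default the
#' input is assumed to be referenced already and recordings are analysed
#' as-is.
#'
#' @param rec An [ssep_recording()].
#' @param reference `"average"` for the common average, or a character vector
#'   of channel labels whose mean serves as reference.
#' @return The re-referenced recording.
#' @export
rereference <- function(rec, reference = "average") {
  stopifnot(inherits(rec, "ssep_recording"))
  ref <- if (identical(reference, "average")) {
    rowMeans(rec$data)
  } else {
    missing <- setdiff(reference, rec$channel_labels)
    if (length(missing)) {
      stop("unknown reference channel(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    rowMeans(rec$data[, reference, drop = FALSE])
  }
  update_data(rec, rec$data - ref)
}

#' Segment a recording into stimulus-locked epochs
#'
#' Epochs are tiled from the stimulus onset with hop
#' `(1 - overlap) * epoch_length`; an incomplete trailing epoch is dropped.
#' Optionally, `include_pre_stim` seconds of pre-stimulus baseline are
#' extracted alongside the first epoch; the baseline is kept separate from
#' the analysis window so spectral estimates are never contaminated by it.
#'
#' @param rec An [ssep_recording()].
#' @param epoch_length Epoch length, seconds (> 0, <= stimulus duration).
#' @param overlap Fractional overlap between consecutive epochs in `[0, 1)`.
#' @param include_pre_stim Pre-stimulus baseline length to extract, seconds.
#' @return An object of class `ssep_epochs`: a list with elements `epochs`
#'   (list of samples x channels matrices), `baseline` (matrix or `NULL`),
#'   and the sampling/stimulus metadata.
#' @export
segment <- function(rec, epoch_length = 4, overlap = 0, include_pre_stim = 0) {
  stopifnot(inherits(rec, "ssep_recording"),
            is_scalar_number(epoch_length), epoch_length > 0,
            is_scalar_number(overlap), overlap >= 0, overlap < 1,
            is_scalar_number(include_pre_stim), include_pre_stim >= 0)
  if (epoch_length > rec$stim_duration) {
    stop("epoch_length exceeds the stimulation duration", call. = FALSE)
  }
  if (include_pre_stim > rec$stim_onset + 1e-9) {
    stop("requested pre-stimulus baseline exceeds the recorded pre-stimulus data",
         call. = FALSE)
  }
  fs <- rec$fs
  n_ep <- round(epoch_length * fs)
  hop <- (1 - overlap) * epoch_length
  hop_samp <- round(hop * fs)
  onset_samp <- round(rec$stim_onset * fs)
  m <- floor((rec$stim_duration - epoch_length) / hop + 1e-9) + 1
  epochs <- lapply(seq_len(m), function(j) {
    i0 <- onset_samp + (j - 1) * hop_samp
    rec$data[(i0 + 1):(i0 + n_ep), , drop = FALSE]
  })
  baseline <- NULL
  if (include_pre_stim > 0) {
    nb <- round(include_pre_stim * fs)
    baseline <- rec$data[(onset_samp - nb + 1):onset_samp, , drop = FALSE]
  }
  structure(
    list(epochs = epochs, baseline = baseline, fs = fs,
         epoch_length = epoch_length, overlap = overlap,
         stim_freq = rec$stim_freq, run_id = rec$run_id,
         channel_labels = rec$channel_labels),
    class = "ssep_epochs"
  )
}

#' Remove the linear DC trend from an epoch
#'
#' Per-channel least-squares removal of intercept and slope. A pure
#' integer-cycle sinusoid is numerically unaffected; ramps and offsets are
#' removed exactly.
#'
#' @param epoch Samples x channels matrix (or vector).
#' @return The detrended epoch, same shape.
#' @export
dc_detrend <- function(epoch) {
  v <- is.vector(epoch)
  if (v) epoch <- matrix(epoch, ncol = 1)
  stopifnot_finite(epoch, "epoch")
  n <- nrow(epoch)
  t <- seq_len(n) - (n + 1) / 2          # centred time axis
  denom <- sum(t^2)
  mu <- colMeans(epoch)
  slope <- as.numeric(crossprod(t, epoch)) / denom
  out <- epoch - rep(mu, each = n) - outer(t, slope)
  if (v) out[, 1] else out
}

#' Baseline-correct an epoch
#'
#' Subtracts a per-channel scalar: the mean of the supplied pre-stimulus
#' baseline when one is available, otherwise the whole-epoch mean (the
#' documented fallback when no pre-stimulus data exist). When a baseline is
#' supplied together with `fs`, it must span at least `min_baseline` seconds.
#'
#' @param epoch Samples x channels matrix (or vector).
#' @param baseline Optional pre-stimulus baseline matrix (same channels).
#' @param fs Sampling rate, Hz; required to enforce the minimum baseline span.
#' @param min_baseline Minimum baseline span, seconds (default 0.2).
#' @return The corrected epoch.
#' @export
baseline_correct <- function(epoch, baseline = NULL, fs = NULL,
                             min_baseline = 0.2) {
  v <- is.vector(epoch)
  if (v) epoch <- matrix(epoch, ncol = 1)
  if (!is.null(baseline)) {
    if (is.vector(baseline)) baseline <- matrix(baseline, ncol = 1)
    stopifnot(ncol(baseline) == ncol(epoch))
    if (!is.null(fs) && nrow(baseline) / fs < min_baseline - 1e-9) {
      stop(sprintf("baseline spans %.3f s; at least %.3f s are required",
                   nrow(baseline) / fs, min_baseline), call. = FALSE)
    }
    mu <- colMeans(baseline)
  } else {
    mu <- colMeans(epoch)
  }
  out <- epoch - rep(mu, each = nrow(epoch))
  if (v) out[, 1] else out
}
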