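#' Single-sided amplitude spectrum of an epoch
#'
#' FFT of the whole epoch (the FFT length equals the epoch length, giving a
#' frequency resolution of `1/epoch_length` Hz), scaled so that a pure
#' sinusoid of amplitude A reads A at its bin. No windowing is applied by
#' default; a Hann window (with its amplitude-correction factor 2) is
#' available as an option.
#'
#' @param x Numeric vector: one epoch of one channel, volts.
#' @param fs Sampling rate, Hz.
#' @param window `"none"` (default) or `"hann"`.
#' @return Data frame with columns `freq` (Hz), `amplitude` (volts) and
#'   `coef` (complex FFT coefficient, same scaling), for bins from DC up to
#'   (but excluding) Nyquist.
#' @export
amplitude_spectrum <- function(x, fs, window = c("none", "hann")) {
  window <- match.arg(window)
  stopifnot(is.numeric(x), length(x) >= 4, is_scalar_number(fs), fs > 0)
  n <- length(x)
  if (window == "hann") {
    w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))
    x <- x * w * 2            # amplitude correction: mean(hann) = 1/2
  }
  X <- stats::fft(x)
  half <- floor(n / 2)
  coef <- X[seq_len(half)] * 2 / n
  coef[1] <- X[1] / n         # DC is not doubled
  data.frame(
    freq = (seq_len(half) - 1) * fs / n,
    amplitude = Mod(coef),
    coef = coef
  )
}

#' Response amplitude at the stimulation frequency
#'
#' The steady-state response amplitude is the single-sided spectral
#' amplitude at the stimulation (modulation) frequency. The target frequency
#' must fall exactly on an FFT bin — i.e. the epoch must contain an integer
#' number of response cycles — otherwise spectral leakage spreads the
#' response over neighbouring bins and the estimate is biased; in that case
#' an error suggests the nearest valid epoch lengths.
#'
#' @inheritParams amplitude_spectrum
#' @param target_freq Stimulation frequency, Hz.
#' @return List with `amplitude` (volts), `bin` (1-based bin index),
#'   `spectrum` (the full data frame from [amplitude_spectrum()]).
#' @export
fft_amplitude <- function(x, fs, target_freq, window = c("none", "hann")) {
  n <- length(x)
  epoch_length <- n / fs
  cycles <- target_freq * epoch_length
  if (!is_whole(cycles, tol = 1e-6)) {
    k <- c(floor(cycles), ceiling(cycles))
    stop(sprintf(
      paste0("epoch of %.4g s does not hold an integer number of %g Hz ",
             "cycles (%.4g); nearest valid epoch lengths are %.4g s and %.4g s"),
      epoch_length, target_freq, cycles,
      k[1] / target_freq, k[2] / target_freq), call. = FALSE)
  }
  spec <- amplitude_spectrum(x, fs, window)
  bin <- as.integer(round(cycles)) + 1L
  if (bin > nrow(spec)) stop("target frequency is at or above Nyquist",
                             call. = FALSE)
  list(amplitude = spec$amplitude[bin], bin = bin, spectrum = spec)
}

#' Residual noise level from flanking FFT bins
#'
#' Estimates the background noise at the response frequency from the
#' amplitudes of the FFT bins within `band_halfwidth` Hz on each side of the
#' response, excluding the response bin itself plus `exclude_bins` guard
#' bins per side (leakage protection). The default band of about 3 Hz per
#' side follows the convention used for residual-noise estimation in ASSR
#' audiometry. The bin amplitudes are combined as their root mean square;
#' a complex-mean variant (`method = "complex"`) is available for
#' sensitivity checks, but since independent noise bins have random phases
#' their complex mean tends to zero and does not measure a noise level.
#'
#' @param spectrum Data frame from [amplitude_spectrum()].
#' @param target_freq Response frequency, Hz.
#' @param band_halfwidth Half-width of the noise band, Hz (default 3).
#' @param exclude_bins Guard bins excluded on each side of the response bin.
#' @param method `"rms"` (default) or `"complex"`.
#' @return Residual noise level, volts.
#' @export
compute_rnl <- function(spectrum, target_freq, band_halfwidth = 3,
                        exclude_bins = 1, method = c("rms", "complex")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(spectrum), all(c("freq", "amplitude") %in% names(spectrum)))
  df <- spectrum$freq[2] - spectrum$freq[1]
  if (target_freq - band_halfwidth <= df / 2) {
    stop("noise band reaches DC; reduce band_halfwidth", call. = FALSE)
  }
  bin <- which.min(abs(spectrum$freq - target_freq))
  in_band <- abs(spectrum$freq - target_freq) <= band_halfwidth + df / 2
  in_band[1] <- FALSE                                  # never include DC
  guard <- abs(seq_len(nrow(spectrum)) - bin) <= exclude_bins
  noise_bins <- which(in_band & !guard)
  if (length(noise_bins) < 4) {
    stop(sprintf("only %d noise bins available; at least 4 are required",
                 length(noise_bins)), call. = FALSE)
  }
  if (method == "rms") {
    sqrt(mean(spectrum$amplitude[noise_bins]^2))
  } else {
    Mod(mean(spectrum$coef[noise_bins]))
  }
}

#' Peak signal-to-noise ratio
#'
#' `pSNR = 10 * log10(amplitude^2 / rnl^2)`, the dB ratio between the squared
#' response amplitude and the squared residual noise level.
#'
#' @param response_amplitude Response amplitude, volts (>= 0).
#' @param rnl Residual noise level, volts (>= 0).
#' @return pSNR in dB. `rnl = 0` returns `Inf` with a warning.
#' @export
compute_psnr <- function(response_amplitude, rnl) {
  stopifnot(response_amplitude >= 0, rnl >= 0)
  if (any(rnl == 0)) {
    warning("zero residual noise level; pSNR is infinite", call. = FALSE)
  }
  10 * log10(response_amplitude^2 / rnl^2)
}

#' Time evolution of amplitude, RNL and pSNR across columns
#'
#' Applies [fft_amplitude()], [compute_rnl()] and [compute_psnr()] to every
#' column (epoch position) and channel of a column-wise averaged series.
#' The time axis is the epoch midpoint relative to stimulus onset, so the
#' resulting curves describe the response amplitude and the recording noise
#' as functions of time during stimulation.
#'
#' @param avg An `ssep_averaged` object from [columnwise_average()].
#' @param target_freq Response frequency, Hz; defaults to the stimulation
#'   frequency stored in `avg`.
#' @param band_halfwidth,exclude_bins,method Passed to [compute_rnl()].
#' @param window Passed to [fft_amplitude()].
#' @return An object of class `ssep_evolution`: a data frame with columns
#'   `column`, `time` (s, epoch midpoint), `channel`, `amplitude` (volts),
#'   `rnl` (volts), `psnr` (dB).
#' @export
evolution <- function(avg, target_freq = NULL, band_halfwidth = 3,
                      exclude_bins = 1, method = "rms", window = "none") {
  stopifnot(inherits(avg, "ssep_averaged"))
  if (is.null(target_freq)) target_freq <- avg$stim_freq
  d <- dim(avg$data)
  m <- d[1]; n_ch <- d[2]
  hop <- (1 - avg$overlap) * avg$epoch_length
  out <- expand.grid(column = seq_len(m), channel = avg$channel_labels,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$time <- (out$column - 1) * hop + avg$epoch_length / 2
  out$amplitude <- NA_real_
  out$rnl <- NA_real_
  row <- 1L
  for (ch in seq_len(n_ch)) {
    for (j in seq_len(m)) {
      fa <- fft_amplitude(avg$data[j, ch, ], avg$fs, target_freq,
                          window = window)
      idx <- which(out$column == j & out$channel == avg$channel_labels[ch])
      out$amplitude[idx] <- fa$amplitude
      out$rnl[idx] <- compute_rnl(fa$spectrum, target_freq,
                                  band_halfwidth = band_halfwidth,
                                  exclude_bins = exclude_bins,
                                  method = method)
    }
  }
  out$psnr <- suppressWarnings(compute_psnr(out$amplitude, out$rnl))
  out <- out[order(out$channel, out$column),
             c("column", "time", "channel", "amplitude", "rnl", "psnr")]
  rownames(out) <- NULL
  class(out) <- c("ssep_evolution", "data.frame")
  out
}
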