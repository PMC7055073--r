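#' A single-run EEG recording
#'
#' Container for one experimental run: a samples-by-channels matrix of
#' voltages plus the stimulus metadata needed downstream (sampling rate,
#' stimulus onset and duration, modulation frequency).
#'
#' @param data Numeric matrix, samples x channels, in volts. A vector is
#'   treated as a single channel.
#' @param fs Sampling rate, Hz (> 0).
#' @param stim_onset Stimulus onset in seconds from the start of the record.
#' @param stim_duration Stimulus duration, seconds.
#' @param stim_freq Stimulation (modulation) frequency, Hz.
#' @param run_id Identifier for the run (character or integer).
#' @param channel_labels Optional channel labels; defaults to the column
#'   names of `data` or `"ch1"`, `"ch2"`, ...
#' @return An object of class `ssep_recording`.
#' @export
ssep_recording <- function(data, fs, stim_onset, stim_duration, stim_freq,
                           run_id = "run1", channel_labels = NULL) {
  if (is.vector(data)) data <- matrix(data, ncol = 1)
  stopifnot(
    is.matrix(data), is.numeric(data),
    is_scalar_number(fs), fs > 0,
    is_scalar_number(stim_onset), stim_onset >= 0,
    is_scalar_number(stim_duration), stim_duration > 0,
    is_scalar_number(stim_freq), stim_freq > 0
  )
  stopifnot_finite(data, "data")
  n <- nrow(data)
  if (stim_onset + stim_duration > n / fs + 1e-9) {
    stop("stimulus window extends beyond the end of the record", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- colnames(data)
    if (is.null(channel_labels)) {
      channel_labels <- paste0("ch", seq_len(ncol(data)))
    }
  }
  stopifnot(length(channel_labels) == ncol(data))
  colnames(data) <- channel_labels
  structure(
    list(
      data = data, fs = fs, stim_onset = stim_onset,
      stim_duration = stim_duration, stim_freq = stim_freq,
      run_id = run_id, channel_labels = channel_labels
    ),
    class = "ssep_recording"
  )
}

#' @export
print.ssep_recording <- function(x, ...) {
  cat(sprintf(
    "<ssep_recording '%s'>  %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
    x$run_id, ncol(x$data), nrow(x$data), x$fs, nrow(x$data) / x$fs
  ))
  cat(sprintf("  stimulus: onset %.3g s, duration %g s, modulation %g Hz\n",
              x$stim_onset, x$stim_duration, x$stim_freq))
  invisible(x)
}

# replace the data matrix, keeping metadata
update_data <- function(rec, data) {
  rec$data <- data
  colnames(rec$data) <- rec$channel_labels
  rec
}

rec_times <- function(rec) (seq_len(nrow(rec$data)) - 1) / rec$fs
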