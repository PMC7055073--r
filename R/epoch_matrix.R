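#' Assemble the runs-by-epochs data matrix
#'
#' Re-arranges segmented runs into the central data structure of the method:
#' an array of `n` runs by `m` epoch positions (by channels by samples),
#' where each column collects the epochs occupying the same temporal
#' position in different runs. All runs must contribute the same number of
#' epochs — epochs must therefore not be rejected before this point, only
#' masked afterwards, or the column structure breaks down.
#'
#' The product `epoch_length * stim_freq` must be an integer, so that the
#' response falls exactly on an FFT bin of the epoch-length spectrum.
#'
#' @param runs List of `ssep_epochs` objects (one per run), see [segment()].
#' @return An object of class `ssep_epoch_matrix`: list with `epochs`
#'   (array `n x m x channels x samples`, volts), `baseline` (array
#'   `n x channels x samples` or `NULL`), `weights` (array
#'   `n x m x channels`, initialised to 1), `rejected` (logical array, all
#'   `FALSE`), and metadata.
#' @export
build_epoch_matrix <- function(runs) {
  stopifnot(is.list(runs), length(runs) >= 1)
  if (!all(vapply(runs, inherits, logical(1), "ssep_epochs"))) {
    stop("`runs` must be a list of segmented runs (see segment())",
         call. = FALSE)
  }
  m <- length(runs[[1]]$epochs)
  for (i in seq_along(runs)) {
    if (length(runs[[i]]$epochs) != m) {
      stop(sprintf(
        "run '%s' has %d epochs where %d were expected; all runs must contribute the same epoch count",
        runs[[i]]$run_id, length(runs[[i]]$epochs), m), call. = FALSE)
    }
  }
  fs <- runs[[1]]$fs
  epoch_length <- runs[[1]]$epoch_length
  stim_freq <- runs[[1]]$stim_freq
  n_ch <- ncol(runs[[1]]$epochs[[1]])
  n_s <- nrow(runs[[1]]$epochs[[1]])
  for (r in runs) {
    stopifnot(r$fs == fs, r$epoch_length == epoch_length,
              ncol(r$epochs[[1]]) == n_ch)
  }
  if (!is_whole(epoch_length * stim_freq)) {
    stop(sprintf(
      "epoch_length * stim_freq = %g must be an integer so the response falls on an exact FFT bin",
      epoch_length * stim_freq), call. = FALSE)
  }
  n <- length(runs)
  epochs <- array(0, dim = c(n, m, n_ch, n_s))
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      epochs[i, j, , ] <- t(runs[[i]]$epochs[[j]])
    }
  }
  baseline <- NULL
  if (!is.null(runs[[1]]$baseline)) {
    nb <- nrow(runs[[1]]$baseline)
    baseline <- array(0, dim = c(n, n_ch, nb))
    for (i in seq_len(n)) baseline[i, , ] <- t(runs[[i]]$baseline)
  }
  structure(
    list(
      epochs = epochs, baseline = baseline,
      weights = array(1, dim = c(n, m, n_ch)),
      rejected = array(FALSE, dim = c(n, m, n_ch)),
      fs = fs, epoch_length = epoch_length, stim_freq = stim_freq,
      overlap = runs[[1]]$overlap,
      run_ids = vapply(runs, function(r) as.character(r$run_id), character(1)),
      channel_labels = runs[[1]]$channel_labels
    ),
    class = "ssep_epoch_matrix"
  )
}

#' @export
print.ssep_epoch_matrix <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf(
    "<ssep_epoch_matrix> %d run(s) x %d epoch position(s), %d channel(s), %d samples/epoch @ %g Hz\n",
    d[1], d[2], d[3], d[4], x$fs))
  cat(sprintf("  epoch length %g s, modulation %g Hz; %d epoch(s) rejected\n",
              x$epoch_length, x$stim_freq, sum(x$rejected)))
  invisible(x)
}

#' Dimensions of an epoch matrix
#' @param x An `ssep_epoch_matrix`.
#' @return Integer vector `(runs, epochs, channels, samples)`.
#' @export
dim.ssep_epoch_matrix <- function(x) dim(x$epochs)

#' Segment and assemble a whole dataset in one step
#'
#' Convenience wrapper: [segment()] every recording, then
#' [build_epoch_matrix()].
#'
#' @param dataset List of [ssep_recording()]s (e.g. an `ssep_dataset`).
#' @inheritParams segment
#' @return An `ssep_epoch_matrix`.
#' @export
epoch_matrix_from_dataset <- function(dataset, epoch_length = 4, overlap = 0,
                                      include_pre_stim = 0) {
  build_epoch_matrix(lapply(dataset, segment, epoch_length = epoch_length,
                            overlap = overlap,
                            include_pre_stim = include_pre_stim))
}
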