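#' Epoch rejection criteria
#'
#' Three classical threshold criteria, each optional:
#' * `gradient` — maximum absolute difference between consecutive samples
#'   (catches motion/muscle spikes);
#' * `maxmin` — peak-to-peak amplitude within the epoch (catches blinks and
#'   slow swings);
#' * `amplitude` — absolute maximum/minimum amplitude (catches saturation
#'   and gross drifts).
#'
#' @param gradient,maxmin,amplitude Thresholds in volts (> 0), or `NULL` to
#'   disable a criterion.
#' @return An object of class `ssep_rejection_criteria`.
#' @export
rejection_criteria <- function(gradient = NULL, maxmin = NULL,
                               amplitude = NULL) {
  for (th in list(gradient, maxmin, amplitude)) {
    if (!is.null(th)) stopifnot(is_scalar_number(th), th > 0)
  }
  structure(list(gradient = gradient, maxmin = maxmin, amplitude = amplitude),
            class = "ssep_rejection_criteria")
}

#' Mark artifact-bearing epochs in the data matrix
#'
#' Sets the rejection mask where any enabled criterion trips; the data are
#' left untouched, so the `n x m` column structure the averaging relies on is
#' preserved. Rejection is idempotent.
#'
#' @param matrix An `ssep_epoch_matrix`.
#' @param criteria A [rejection_criteria()].
#' @param granularity `"channel"` (default) rejects per (run, epoch, channel);
#'   `"any"` rejects the epoch on all channels when any channel trips —
#'   useful for single-channel analyses driven by a frontal EOG proxy.
#' @param verbose Log the rejection count.
#' @return The matrix with its `rejected` mask (and `weights`) updated;
#'   weights of rejected epochs are set to 0.
#' @export
reject_epochs <- function(matrix, criteria, granularity = c("channel", "any"),
                          verbose = FALSE) {
  stopifnot(inherits(matrix, "ssep_epoch_matrix"),
            inherits(criteria, "ssep_rejection_criteria"))
  granularity <- match.arg(granularity)
  d <- dim(matrix$epochs)
  n <- d[1]; m <- d[2]; n_ch <- d[3]
  newly <- array(FALSE, dim = c(n, m, n_ch))
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      for (ch in seq_len(n_ch)) {
        x <- matrix$epochs[i, j, ch, ]
        trip <- FALSE
        if (!is.null(criteria$gradient)) {
          trip <- trip || max(abs(diff(x))) > criteria$gradient
        }
        if (!trip && !is.null(criteria$maxmin)) {
          trip <- trip || (max(x) - min(x)) > criteria$maxmin
        }
        if (!trip && !is.null(criteria$amplitude)) {
          trip <- trip || max(abs(x)) > criteria$amplitude
        }
        newly[i, j, ch] <- trip
      }
    }
  }
  if (granularity == "any") {
    for (i in seq_len(n)) for (j in seq_len(m)) {
      if (any(newly[i, j, ])) newly[i, j, ] <- TRUE
    }
  }
  matrix$rejected <- matrix$rejected | newly
  matrix$weights[matrix$rejected] <- 0
  for (j in seq_len(m)) {
    for (ch in seq_len(n_ch)) {
      if (all(matrix$rejected[, j, ch])) {
        stop(sprintf(
          "all epochs of column %d (channel %s) are rejected; its average would be undefined",
          j, matrix$channel_labels[ch]), call. = FALSE)
      }
    }
  }
  if (verbose) {
    message(sprintf("rejected %d of %d epochs", sum(matrix$rejected),
                    length(matrix$rejected)))
  }
  matrix
}

#' Inverse-variance epoch weights
#'
#' Each epoch is weighted by the reciprocal of its sample variance, so noisy
#' epochs (motion, muscle activity) contribute less to the column average.
#' The column average later normalises by the sum of weights of the
#' contributing epochs, which keeps the output in volts. Rejected epochs get
#' weight 0.
#'
#' @param matrix An `ssep_epoch_matrix`.
#' @return The matrix with `weights` filled in (units 1/volts^2).
#' @export
compute_weights <- function(matrix) {
  stopifnot(inherits(matrix, "ssep_epoch_matrix"))
  d <- dim(matrix$epochs)
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      for (ch in seq_len(d[3])) {
        if (matrix$rejected[i, j, ch]) {
          matrix$weights[i, j, ch] <- 0
          next
        }
        v <- stats::var(matrix$epochs[i, j, ch, ])
        if (v <= 0) {
          stop(sprintf(
            "epoch (run %d, column %d, channel %s) has zero variance; cannot weight by 1/variance",
            i, j, matrix$channel_labels[ch]), call. = FALSE)
        }
        matrix$weights[i, j, ch] <- 1 / v
      }
    }
  }
  matrix
}

#' Run-level quality control by response-amplitude drop
#'
#' Flags experimental runs whose steady-state amplitude has dropped by more
#' than `threshold_fraction` below a reference amplitude — the online check
#' used to detect waning attention or vigilance across a session. The
#' reference defaults to the mean amplitude of the first `n_reference`
#' run(s). The comparison is a strict inequality: a run at exactly
#' `(1 - threshold_fraction) * reference` is kept.
#'
#' @param amplitudes Per-run response amplitudes, volts (>= 0), in
#'   acquisition order.
#' @param reference Reference amplitude, volts; default derived from the
#'   first `n_reference` runs.
#' @param threshold_fraction Allowed fractional drop (default 0.05).
#' @param n_reference Number of initial runs defining the reference.
#' @param run_ids Optional run identifiers.
#' @return An object of class `ssep_run_qc`: amplitudes, reference, flags.
#' @export
run_qc <- function(amplitudes, reference = NULL, threshold_fraction = 0.05,
                   n_reference = 1, run_ids = NULL) {
  if (length(amplitudes) == 0) stop("no amplitudes supplied", call. = FALSE)
  stopifnot(all(amplitudes >= 0),
            threshold_fraction > 0, threshold_fraction < 1)
  if (is.null(reference)) {
    reference <- mean(amplitudes[seq_len(min(n_reference, length(amplitudes)))])
  }
  stopifnot(is_scalar_number(reference), reference > 0)
  if (is.null(run_ids)) run_ids <- seq_along(amplitudes)
  flagged <- amplitudes < (1 - threshold_fraction) * reference
  structure(
    list(amplitudes = amplitudes, reference = reference,
         threshold_fraction = threshold_fraction,
         rejected_runs = run_ids[flagged], flagged = flagged,
         run_ids = run_ids),
    class = "ssep_run_qc"
  )
}

#' @export
print.ssep_run_qc <- function(x, ...) {
  cat(sprintf(
    "<ssep_run_qc> %d run(s), reference %.3g uV, threshold drop %g%%\n",
    length(x$amplitudes), volts_to_uV(x$reference),
    100 * x$threshold_fraction))
  if (any(x$flagged)) {
    cat("  flagged:", paste(x$run_ids[x$flagged], collapse = ", "), "\n")
  } else {
    cat("  no runs flagged\n")
  }
  invisible(x)
}

#' Rejection report as a data frame
#'
#' @param matrix An `ssep_epoch_matrix` after [reject_epochs()].
#' @return Data frame with one row per (run, column, channel) and a logical
#'   `rejected` column.
#' @export
rejection_report <- function(matrix) {
  stopifnot(inherits(matrix, "ssep_epoch_matrix"))
  d <- dim(matrix$epochs)
  expand <- expand.grid(run = seq_len(d[1]), column = seq_len(d[2]),
                        channel = matrix$channel_labels,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  expand$run_id <- matrix$run_ids[expand$run]
  expand$rejected <- as.vector(matrix$rejected)
  expand$weight <- as.vector(matrix$weights)
  expand
}
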