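#' Column-wise (across-run) weighted average
#'
#' The core of the method: for every epoch position (column) the epochs
#' occupying that position in the different runs are averaged sample-wise,
#' so the averaged waveform at column j reflects the instantaneous response
#' at that point of the stimulation interval — epochs are never averaged
#' across positions within a run. The weighted average of column j, channel
#' c is
#' \deqn{\bar{x}_{j c}(s) = \frac{\sum_i w_{i j c}\, x_{i j c}(s)}
#'                               {\sum_i w_{i j c}}}
#' over the non-rejected epochs of the first `k` runs; normalising by the
#' sum of weights keeps the output in volts. With unit weights this is the
#' arithmetic mean across runs.
#'
#' @param matrix An `ssep_epoch_matrix`.
#' @param k Number of runs to average (the first `k` in acquisition order);
#'   default all.
#' @param use_weights Use the stored weights (default) or force unit weights.
#' @return An object of class `ssep_averaged`: list with `data` (array
#'   `m x channels x samples`, volts), `baseline` (array
#'   `channels x samples` or `NULL`, averaged the same way with the weights
#'   of column 1), `effective_n` (matrix `m x channels` of contributing
#'   epochs), and metadata.
#' @export
columnwise_average <- function(matrix, k = NULL, use_weights = TRUE) {
  stopifnot(inherits(matrix, "ssep_epoch_matrix"))
  d <- dim(matrix$epochs)
  n <- d[1]; m <- d[2]; n_ch <- d[3]; n_s <- d[4]
  if (is.null(k)) k <- n
  stopifnot(k >= 1, k <= n)
  w_all <- if (use_weights) matrix$weights else
    array(1, dim = dim(matrix$weights)) * !matrix$rejected
  if (use_weights) w_all[matrix$rejected] <- 0
  out <- array(0, dim = c(m, n_ch, n_s))
  eff <- matrix(0L, m, n_ch)
  for (j in seq_len(m)) {
    for (ch in seq_len(n_ch)) {
      w <- w_all[seq_len(k), j, ch]
      contributors <- which(w > 0)
      if (length(contributors) == 0) {
        stop(sprintf(
          "column %d (channel %s) has no non-rejected epochs among the first %d run(s)",
          j, matrix$channel_labels[ch], k), call. = FALSE)
      }
      x <- matrix$epochs[contributors, j, ch, , drop = FALSE]
      dim(x) <- c(length(contributors), n_s)
      out[j, ch, ] <- colSums(x * w[contributors]) / sum(w[contributors])
      eff[j, ch] <- length(contributors)
    }
  }
  baseline <- NULL
  if (!is.null(matrix$baseline)) {
    baseline <- matrix(0, n_ch, dim(matrix$baseline)[3])
    for (ch in seq_len(n_ch)) {
      w <- w_all[seq_len(k), 1, ch]
      contributors <- which(w > 0)
      b <- matrix$baseline[contributors, ch, , drop = FALSE]
      dim(b) <- c(length(contributors), dim(matrix$baseline)[3])
      baseline[ch, ] <- colSums(b * w[contributors]) / sum(w[contributors])
    }
  }
  structure(
    list(data = out, baseline = baseline, effective_n = eff,
         n_runs_used = as.integer(k), fs = matrix$fs,
         epoch_length = matrix$epoch_length, stim_freq = matrix$stim_freq,
         overlap = matrix$overlap, channel_labels = matrix$channel_labels),
    class = "ssep_averaged"
  )
}

#' @export
print.ssep_averaged <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<ssep_averaged> %d column(s) x %d channel(s) x %d samples, averaged over %d run(s)\n",
    d[1], d[2], d[3], x$n_runs_used))
  invisible(x)
}

#' Classical sequential (within-run) average
#'
#' Averages the `m` consecutive epochs of a single run — the classical
#' steady-state estimator, which assumes a stationary response. For a
#' response whose amplitude evolves during stimulation this average
#' conflates the dynamics: its amplitude approximates the time-mean of the
#' envelope, not its instantaneous value. Provided for comparison with the
#' column-wise estimator.
#'
#' @param matrix An `ssep_epoch_matrix`.
#' @param run_index Which run to average.
#' @param use_weights Use stored epoch weights (default unit weights).
#' @return Matrix `channels x samples`: the within-run average epoch.
#' @export
sequential_average <- function(matrix, run_index = 1, use_weights = FALSE) {
  stopifnot(inherits(matrix, "ssep_epoch_matrix"))
  d <- dim(matrix$epochs)
  stopifnot(run_index >= 1, run_index <= d[1])
  m <- d[2]; n_ch <- d[3]; n_s <- d[4]
  out <- matrix(0, n_ch, n_s)
  for (ch in seq_len(n_ch)) {
    w <- if (use_weights) matrix$weights[run_index, , ch] else
      as.numeric(!matrix$rejected[run_index, , ch])
    contributors <- which(w > 0)
    if (!length(contributors)) {
      stop("all epochs of this run are rejected", call. = FALSE)
    }
    x <- matrix$epochs[run_index, contributors, ch, , drop = FALSE]
    dim(x) <- c(length(contributors), n_s)
    out[ch, ] <- colSums(x * w[contributors]) / sum(w[contributors])
  }
  out
}

#' Progressive-averaging curves
#'
#' For each k = 1..n, averages the first k runs column-wise, extracts
#' amplitude, RNL and pSNR per column, and summarises each quantity by its
#' mean and standard deviation across the m columns. These curves show how
#' the estimates stabilise as runs are accumulated: the RNL falls as
#' 1/sqrt(k) while the response amplitude converges to the true envelope
#' mean, so the pSNR grows by about `10*log10(k)` dB.
#'
#' @param matrix An `ssep_epoch_matrix`.
#' @param k_values Integer vector of k values (default `1:n`).
#' @param order `"acquisition"` (default) or `"shuffled"`; shuffling uses
#'   `shuffle_seed`.
#' @param shuffle_seed Seed for the shuffled order.
#' @param use_weights Passed to [columnwise_average()].
#' @param ... Passed to [evolution()] (noise band, window, ...).
#' @return An object of class `ssep_progressive`: a data frame with columns
#'   `k`, `channel`, and mean/sd of `amplitude` (volts), `rnl` (volts),
#'   `psnr` (dB) across columns.
#' @export
progressive_curves <- function(matrix, k_values = NULL,
                               order = c("acquisition", "shuffled"),
                               shuffle_seed = 1L, use_weights = TRUE, ...) {
  stopifnot(inherits(matrix, "ssep_epoch_matrix"))
  order <- match.arg(order)
  n <- dim(matrix$epochs)[1]
  if (is.null(k_values)) k_values <- seq_len(n)
  stopifnot(all(k_values >= 1), all(k_values <= n), !is.unsorted(k_values))
  if (order == "shuffled") {
    perm <- with_local_seed(shuffle_seed, sample.int(n))
    matrix$epochs <- matrix$epochs[perm, , , , drop = FALSE]
    matrix$weights <- matrix$weights[perm, , , drop = FALSE]
    matrix$rejected <- matrix$rejected[perm, , , drop = FALSE]
  }
  res <- list()
  for (k in k_values) {
    avg <- columnwise_average(matrix, k = k, use_weights = use_weights)
    ev <- evolution(avg, ...)
    agg <- do.call(rbind, lapply(split(ev, ev$channel), function(g) {
      data.frame(
        k = k, channel = g$channel[1],
        amplitude_mean = mean(g$amplitude), amplitude_sd = stats::sd(g$amplitude),
        rnl_mean = mean(g$rnl), rnl_sd = stats::sd(g$rnl),
        psnr_mean = mean(g$psnr), psnr_sd = stats::sd(g$psnr)
      )
    }))
    res[[length(res) + 1]] <- agg
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("ssep_progressive", "data.frame")
  out
}
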