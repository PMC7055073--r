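#' Fit the time evolution of a steady-state evoked response
#'
#' The main entry point: takes a set of repeated stimulation runs (or an
#' already-assembled epoch matrix), optionally rejects artifact-bearing
#' epochs and weights the rest by inverse variance, column-wise averages
#' across runs, and extracts the response amplitude, residual noise level
#' and peak SNR per epoch position — the time evolution of the response —
#' together with progressive-averaging curves describing how the estimates
#' converge as runs accumulate.
#'
#' @param x A list of [ssep_recording()]s (e.g. from [simulate_dataset()] or
#'   [read_dataset()]) or an `ssep_epoch_matrix`.
#' @param epoch_length Epoch length in seconds (used when `x` holds
#'   recordings); `epoch_length * stim_freq` must be an integer.
#' @param overlap Fractional epoch overlap in `[0, 1)`.
#' @param include_pre_stim Pre-stimulus baseline to carry with column 1, s.
#' @param detrend DC-detrend every epoch before assembly (default `TRUE`).
#' @param baseline Baseline-correct every epoch (`"pre"` uses the
#'   pre-stimulus baseline and requires `include_pre_stim >= 0.2`; `"epoch"`
#'   subtracts the whole-epoch mean; `"none"` disables).
#' @param criteria Optional [rejection_criteria()].
#' @param weighting `"variance"` (inverse-variance weights, default) or
#'   `"uniform"`.
#' @param target_freq Response frequency, Hz; defaults to the stimulation
#'   frequency carried by the data.
#' @param band_halfwidth RNL noise band half-width, Hz (default 3).
#' @param exclude_bins Guard bins excluded around the response bin.
#' @param k_values k schedule for the progressive curves (default `1:n`).
#' @param progressive Compute progressive curves (default `TRUE`; the
#'   evolution curve alone is much cheaper).
#' @param window FFT window, `"none"` (default) or `"hann"`.
#' @return An object of class `ssep_track` with components `matrix`
#'   (the weighted, masked epoch matrix), `average` (the full column-wise
#'   average), `evolution` (per-column amplitude/RNL/pSNR), `progressive`
#'   (per-k summaries or `NULL`) and the call/settings. Methods: `print`,
#'   `summary`, `coef` (per-column amplitudes), `plot`, `as.data.frame`,
#'   `fitted` (averaged waveforms).
#' @export
#' @examples
#' cfg <- ssep_sim_config(n_runs = 4, stim_duration = 8, fs = 128, seed = 7)
#' fit <- ssep_track(simulate_dataset(cfg), epoch_length = 2,
#'                   progressive = FALSE)
#' coef(fit)
ssep_track <- function(x, epoch_length = 4, overlap = 0,
                       include_pre_stim = 0, detrend = TRUE,
                       baseline = c("none", "pre", "epoch"),
                       criteria = NULL,
                       weighting = c("variance", "uniform"),
                       target_freq = NULL, band_halfwidth = 3,
                       exclude_bins = 1, k_values = NULL,
                       progressive = TRUE, window = "none") {
  baseline <- match.arg(baseline)
  weighting <- match.arg(weighting)
  cl <- match.call()

  if (inherits(x, "ssep_epoch_matrix")) {
    mat <- x
  } else {
    if (!is.list(x) || !all(vapply(x, inherits, logical(1), "ssep_recording"))) {
      stop("`x` must be a list of ssep_recording objects or an ssep_epoch_matrix",
           call. = FALSE)
    }
    if (baseline == "pre" && include_pre_stim < 0.2) {
      stop("baseline = \"pre\" requires include_pre_stim >= 0.2 s", call. = FALSE)
    }
    runs <- lapply(x, function(rec) {
      seg <- segment(rec, epoch_length = epoch_length, overlap = overlap,
                     include_pre_stim = include_pre_stim)
      if (detrend) seg$epochs <- lapply(seg$epochs, dc_detrend)
      if (baseline == "pre") {
        seg$epochs <- lapply(seg$epochs, baseline_correct,
                             baseline = seg$baseline, fs = seg$fs)
      } else if (baseline == "epoch") {
        seg$epochs <- lapply(seg$epochs, baseline_correct)
      }
      seg
    })
    mat <- build_epoch_matrix(runs)
  }

  if (!is.null(criteria)) mat <- reject_epochs(mat, criteria)
  if (weighting == "variance") mat <- compute_weights(mat)

  avg <- columnwise_average(mat, use_weights = TRUE)
  ev <- evolution(avg, target_freq = target_freq,
                  band_halfwidth = band_halfwidth,
                  exclude_bins = exclude_bins, window = window)
  prog <- NULL
  if (progressive && dim(mat$epochs)[1] >= 2) {
    prog <- progressive_curves(mat, k_values = k_values,
                               target_freq = target_freq,
                               band_halfwidth = band_halfwidth,
                               exclude_bins = exclude_bins, window = window)
  } else if (progressive) {
    warning("only one run supplied; progressive curves degenerate to k = 1",
            call. = FALSE)
    prog <- progressive_curves(mat, k_values = 1L, target_freq = target_freq,
                               band_halfwidth = band_halfwidth,
                               exclude_bins = exclude_bins, window = window)
  }

  structure(
    list(matrix = mat, average = avg, evolution = ev, progressive = prog,
         settings = list(
           epoch_length = mat$epoch_length, overlap = mat$overlap,
           target_freq = if (is.null(target_freq)) mat$stim_freq else target_freq,
           band_halfwidth = band_halfwidth, exclude_bins = exclude_bins,
           weighting = weighting, window = window
         ),
         call = cl),
    class = "ssep_track"
  )
}

#' @export
print.ssep_track <- function(x, ...) {
  d <- dim(x$matrix$epochs)
  cat("Steady-state response time course (column-wise averaging)\n")
  cat(sprintf("  data matrix: %d run(s) x %d epoch position(s), %d channel(s), epoch %g s @ %g Hz\n",
              d[1], d[2], d[3], x$matrix$epoch_length, x$matrix$fs))
  cat(sprintf("  response frequency %g Hz; RNL band +/- %g Hz; weighting: %s\n",
              x$settings$target_freq, x$settings$band_halfwidth,
              x$settings$weighting))
  cat(sprintf("  epochs rejected: %d of %d\n", sum(x$matrix$rejected),
              length(x$matrix$rejected)))
  cat("\nAmplitude time course (uV) by column:\n")
  ev <- x$evolution
  for (ch in unique(ev$channel)) {
    g <- ev[ev$channel == ch, ]
    cat(sprintf("  %s: %s\n", ch,
                paste(sprintf("%.2f", volts_to_uV(g$amplitude)), collapse = " ")))
  }
  invisible(x)
}

#' @export
summary.ssep_track <- function(object, ...) {
  ev <- object$evolution
  s <- list(
    n_runs = dim(object$matrix$epochs)[1],
    n_columns = dim(object$matrix$epochs)[2],
    n_rejected = sum(object$matrix$rejected),
    evolution = ev,
    amplitude_uV = volts_to_uV(ev$amplitude),
    peak_column = ev$column[which.max(ev$amplitude)],
    peak_time = ev$time[which.max(ev$amplitude)],
    mean_rnl_uV = volts_to_uV(mean(ev$rnl)),
    mean_psnr_dB = mean(ev$psnr),
    settings = object$settings
  )
  class(s) <- "summary.ssep_track"
  s
}

#' @export
print.summary.ssep_track <- function(x, ...) {
  cat(sprintf("Column-wise averaged steady-state response: %d runs x %d columns, %d epoch(s) rejected\n",
              x$n_runs, x$n_columns, x$n_rejected))
  cat(sprintf("  amplitude peaks at column %d (t = %.1f s): %.2f uV\n",
              x$peak_column, x$peak_time, max(x$amplitude_uV)))
  cat(sprintf("  mean RNL %.3f uV; mean pSNR %.1f dB\n",
              x$mean_rnl_uV, x$mean_psnr_dB))
  ev <- x$evolution
  df <- data.frame(column = ev$column, time_s = ev$time, channel = ev$channel,
                   amplitude_uV = round(volts_to_uV(ev$amplitude), 3),
                   rnl_uV = round(volts_to_uV(ev$rnl), 3),
                   psnr_dB = round(ev$psnr, 2))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ssep_track <- function(object, ...) {
  ev <- object$evolution
  chans <- unique(ev$channel)
  if (length(chans) == 1) {
    stats::setNames(ev$amplitude, paste0("col", ev$column))
  } else {
    out <- sapply(chans, function(ch) ev$amplitude[ev$channel == ch])
    rownames(out) <- paste0("col", unique(ev$column))
    out
  }
}

#' @export
fitted.ssep_track <- function(object, ...) object$average$data

#' @export
as.data.frame.ssep_track <- function(x, ...) {
  out <- x$evolution
  class(out) <- "data.frame"
  out
}

#' Plot amplitude, RNL and pSNR for a fitted time course
#'
#' Base-graphics panels: the amplitude and RNL time courses versus epoch
#' midpoint time (and, when available, the progressive curves versus the
#' number of averaged runs with a +/- 1 SD band across columns).
#'
#' @param x An `ssep_track` object.
#' @param which `"evolution"`, `"progressive"`, or `"both"` (default:
#'   evolution; progressive added when present).
#' @param channel Channel label to plot (default: first).
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.ssep_track <- function(x, which = c("both", "evolution", "progressive"),
                            channel = NULL, ...) {
  which <- match.arg(which)
  ev <- x$evolution
  if (is.null(channel)) channel <- ev$channel[1]
  ev <- ev[ev$channel == channel, ]
  show_prog <- which %in% c("both", "progressive") && !is.null(x$progressive)
  show_ev <- which %in% c("both", "evolution")
  n_panels <- 2 * show_ev + 3 * show_prog
  op <- graphics::par(mfrow = c(if (show_ev && show_prog) 2 else 1,
                                max(2, if (show_prog) 3 else 2)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  if (show_ev) {
    graphics::plot(ev$time, volts_to_uV(ev$amplitude), type = "b", pch = 16,
                   xlab = "time from stimulus onset (s)",
                   ylab = "amplitude (uV)", main = "response amplitude")
    graphics::plot(ev$time, volts_to_uV(ev$rnl), type = "b", pch = 16,
                   xlab = "time from stimulus onset (s)",
                   ylab = "RNL (uV)", main = "residual noise level")
  }
  if (show_prog) {
    pg <- x$progressive
    pg <- pg[pg$channel == channel, ]
    band_plot <- function(k, m, s, ylab, main) {
      ylim <- range(c(m - s, m + s), finite = TRUE)
      graphics::plot(k, m, type = "n", ylim = ylim,
                     xlab = "runs averaged (k)", ylab = ylab, main = main)
      graphics::polygon(c(k, rev(k)), c(m - s, rev(m + s)),
                        col = grDevices::grey(0.85), border = NA)
      graphics::lines(k, m, lwd = 2)
    }
    band_plot(pg$k, volts_to_uV(pg$amplitude_mean), volts_to_uV(pg$amplitude_sd),
              "amplitude (uV)", "amplitude vs runs averaged")
    band_plot(pg$k, volts_to_uV(pg$rnl_mean), volts_to_uV(pg$rnl_sd),
              "RNL (uV)", "RNL vs runs averaged")
    band_plot(pg$k, pg$psnr_mean, pg$psnr_sd, "pSNR (dB)",
              "pSNR vs runs averaged")
  }
  invisible(x)
}
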