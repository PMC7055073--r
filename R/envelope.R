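#' Response-envelope parameters: onset integration, adaptation, extinction
#'
#' Defines the instantaneous amplitude of the steady-state response as a
#' smooth "rise times adaptation" product. During stimulation the envelope is
#'
#' \deqn{e(t) = (1 - e^{-t/\tau_r}) \cdot
#'   \left[A_p + (A_0 - A_p)\, e^{-\max(0,\, t - t_{peak})/\tau_a}\right]}
#'
#' where \eqn{\tau_r} is the onset-integration time constant, \eqn{A_0} the
#' pre-adaptation (peak) amplitude, \eqn{A_p} the adapted plateau amplitude,
#' \eqn{t_{peak}} the time at which adaptation sets in, and \eqn{\tau_a} the
#' adaptation time constant. After stimulus offset the envelope decays
#' exponentially with time constant `offset_tau` from its value at offset.
#' The curve is continuous everywhere, starts at exactly 0, and tends to
#' `plateau_amplitude` for a long stimulus.
#'
#' The defaults emulate a response that builds up over roughly the first 12 s
#' of stimulation, adapts over the following stretch, and settles on a
#' plateau — the qualitative time course reported for human SSVEPs under
#' sustained 10 Hz amplitude-modulated light.
#'
#' @param baseline_amplitude Pre-adaptation (peak) response amplitude, volts.
#' @param rise_tau Onset-integration time constant, seconds (> 0).
#' @param adapt_tau Adaptation (exponential decay) time constant, seconds (> 0).
#' @param plateau_amplitude Adapted steady amplitude, volts.
#' @param peak_time Time after stimulus onset at which adaptation begins,
#'   seconds; must lie within the stimulus when evaluated.
#' @param offset_tau Extinction time constant after stimulus end, seconds (> 0).
#' @return An object of class `ssep_envelope`.
#' @seealso [envelope_value()], [envelope_piecewise()]
#' @export
#' @examples
#' env <- envelope_params()
#' t <- seq(0, 45, by = 0.01)
#' e <- envelope_value(env, t, stim_duration = 40)
envelope_params <- function(baseline_amplitude = 2e-6,
                            rise_tau = 4,
                            adapt_tau = 6,
                            plateau_amplitude = 1.2e-6,
                            peak_time = 12,
                            offset_tau = 0.5) {
  stopifnot(
    is_scalar_number(baseline_amplitude), baseline_amplitude >= 0,
    is_scalar_number(plateau_amplitude), plateau_amplitude >= 0,
    is_scalar_number(rise_tau), rise_tau > 0,
    is_scalar_number(adapt_tau), adapt_tau > 0,
    is_scalar_number(offset_tau), offset_tau > 0,
    is_scalar_number(peak_time), peak_time >= 0
  )
  structure(
    list(
      baseline_amplitude = baseline_amplitude,
      rise_tau = rise_tau,
      adapt_tau = adapt_tau,
      plateau_amplitude = plateau_amplitude,
      peak_time = peak_time,
      offset_tau = offset_tau
    ),
    class = "ssep_envelope"
  )
}

#' Piecewise-linear response envelope
#'
#' An alternative envelope defined by linear interpolation between knots,
#' useful for constructing exactly-known test envelopes (e.g. a linear decay
#' from 1 to 0 across the stimulation interval). Outside the stimulation
#' interval the envelope is 0; within it, values are interpolated (and held
#' constant beyond the last knot).
#'
#' @param times Knot times in seconds from stimulus onset (non-decreasing).
#' @param amplitudes Envelope values at the knots, volts (>= 0).
#' @return An object of class `ssep_envelope_pw`.
#' @export
envelope_piecewise <- function(times, amplitudes) {
  stopifnot(
    length(times) == length(amplitudes), length(times) >= 1,
    !is.unsorted(times), all(amplitudes >= 0), all(times >= 0)
  )
  structure(list(times = times, amplitudes = amplitudes),
            class = "ssep_envelope_pw")
}

#' Evaluate a response envelope
#'
#' @param env An envelope object ([envelope_params()] or
#'   [envelope_piecewise()]).
#' @param t Times in seconds from stimulus onset (>= 0); vectorised.
#' @param stim_duration Stimulus duration in seconds.
#' @return Instantaneous response amplitude in volts, same length as `t`.
#' @export
envelope_value <- function(env, t, stim_duration) {
  UseMethod("envelope_value")
}

#' @export
envelope_value.ssep_envelope <- function(env, t, stim_duration) {
  if (any(t < 0)) stop("envelope is defined for t >= 0 only", call. = FALSE)
  stopifnot(is_scalar_number(stim_duration), stim_duration > 0)
  if (env$peak_time > stim_duration) {
    stop("`peak_time` must lie within the stimulus duration", call. = FALSE)
  }
  on_val <- function(tt) {
    rise <- 1 - exp(-tt / env$rise_tau)
    adapt <- env$plateau_amplitude +
      (env$baseline_amplitude - env$plateau_amplitude) *
        exp(-pmax(0, tt - env$peak_time) / env$adapt_tau)
    rise * adapt
  }
  out <- numeric(length(t))
  on <- t <= stim_duration
  out[on] <- on_val(t[on])
  if (any(!on)) {
    # continuous exponential extinction from the offset value
    e_end <- on_val(stim_duration)
    out[!on] <- e_end * exp(-(t[!on] - stim_duration) / env$offset_tau)
  }
  out
}

#' @export
envelope_value.ssep_envelope_pw <- function(env, t, stim_duration) {
  if (any(t < 0)) stop("envelope is defined for t >= 0 only", call. = FALSE)
  out <- stats::approx(env$times, env$amplitudes, xout = pmin(t, max(env$times)),
                       rule = 2)$y
  out[t >= stim_duration] <- 0
  out
}

#' Per-epoch mean of the true envelope
#'
#' Averages the ground-truth envelope over consecutive analysis epochs. This
#' is the quantity a per-column spectral amplitude estimate should recover:
#' the fundamental FFT bin of an amplitude-modulated sinusoid measures the
#' epoch-mean of its (slowly varying) envelope.
#'
#' @inheritParams envelope_value
#' @param epoch_length Epoch length, seconds.
#' @param overlap Fractional overlap between consecutive epochs in `[0, 1)`.
#' @param dt Integration grid step, seconds.
#' @return Numeric vector of per-epoch mean amplitudes (volts), one per epoch.
#' @export
envelope_epoch_means <- function(env, stim_duration, epoch_length,
                                 overlap = 0, dt = 1e-3) {
  hop <- (1 - overlap) * epoch_length
  n_epochs <- floor((stim_duration - epoch_length) / hop + 1e-9) + 1
  vapply(seq_len(n_epochs), function(j) {
    t0 <- (j - 1) * hop
    tt <- seq(t0, t0 + epoch_length, by = dt)
    mean(envelope_value(env, tt, stim_duration))
  }, numeric(1))
}
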