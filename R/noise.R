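#' Background-noise parameters for the simulator
#'
#' White plus power-law ("pink") background activity, with optional
#' narrowband alpha bursts. The pink component is synthesised by spectral
#' shaping of Gaussian white noise: the amplitude of each positive-frequency
#' bin is multiplied by \eqn{f^{-\alpha/2}} so the power spectral density
#' falls off as \eqn{1/f^\alpha}, then the series is rescaled to the
#' requested standard deviation.
#'
#' @param white_sd Standard deviation of the white component, volts.
#' @param pink_sd Standard deviation of the pink component, volts.
#' @param pink_exponent Spectral slope alpha in `[0, 2]`.
#' @param alpha_burst_rate Rate of 8-12 Hz narrowband bursts, events/min.
#' @param alpha_burst_amplitude Peak amplitude of a burst, volts.
#' @return An object of class `ssep_noise`.
#' @export
noise_params <- function(white_sd = 4e-6, pink_sd = 8e-6, pink_exponent = 1,
                         alpha_burst_rate = 0, alpha_burst_amplitude = 10e-6) {
  stopifnot(
    is_scalar_number(white_sd), white_sd >= 0,
    is_scalar_number(pink_sd), pink_sd >= 0,
    is_scalar_number(pink_exponent), pink_exponent >= 0, pink_exponent <= 2,
    is_scalar_number(alpha_burst_rate), alpha_burst_rate >= 0,
    is_scalar_number(alpha_burst_amplitude), alpha_burst_amplitude >= 0
  )
  structure(
    list(white_sd = white_sd, pink_sd = pink_sd,
         pink_exponent = pink_exponent,
         alpha_burst_rate = alpha_burst_rate,
         alpha_burst_amplitude = alpha_burst_amplitude),
    class = "ssep_noise"
  )
}

#' Artifact parameters for the simulator
#'
#' Blinks are positive half-period raised-cosine transients (large
#' peak-to-peak excursions that the max-min and amplitude rejection criteria
#' should catch); motion spikes are single-sample transients (sharp
#' sample-to-sample jumps that the gradient criterion should catch).
#'
#' @param blink_rate Blink rate, events/min (>= 0).
#' @param blink_amplitude Blink peak amplitude, volts.
#' @param blink_width Blink duration, seconds (> 0).
#' @param spike_rate Motion-spike rate, events/min (>= 0).
#' @param spike_amplitude Spike amplitude, volts.
#' @return An object of class `ssep_artifacts`.
#' @export
artifact_params <- function(blink_rate = 0, blink_amplitude = 150e-6,
                            blink_width = 0.3, spike_rate = 0,
                            spike_amplitude = 100e-6) {
  stopifnot(
    is_scalar_number(blink_rate), blink_rate >= 0,
    is_scalar_number(spike_rate), spike_rate >= 0,
    is_scalar_number(blink_width), blink_width > 0,
    is_scalar_number(blink_amplitude), blink_amplitude >= 0,
    is_scalar_number(spike_amplitude), spike_amplitude >= 0
  )
  structure(
    list(blink_rate = blink_rate, blink_amplitude = blink_amplitude,
         blink_width = blink_width, spike_rate = spike_rate,
         spike_amplitude = spike_amplitude),
    class = "ssep_artifacts"
  )
}

# Pink (1/f^alpha) noise by spectral shaping; returns a length-n vector with
# sd `sd`. alpha = 0 degenerates to white noise.
pink_noise <- function(n, sd, alpha) {
  if (sd == 0 || n == 0) return(numeric(n))
  w <- stats::rnorm(n)
  if (alpha == 0) return(w * sd / stats::sd(w))
  X <- stats::fft(w)
  freq_idx <- c(0, seq_len(n - 1))
  # fold to two-sided frequency magnitudes; DC removed
  k <- pmin(freq_idx, n - freq_idx)
  gain <- c(0, k[-1]^(-alpha / 2))
  x <- Re(stats::fft(X * gain, inverse = TRUE)) / n
  x * sd / stats::sd(x)
}

# Event times (seconds) for a Poisson process at `rate` events/min over
# `duration` seconds.
poisson_events <- function(rate, duration) {
  n <- stats::rpois(1, rate * duration / 60)
  sort(stats::runif(n, 0, duration))
}

# Add raised-cosine blinks and single-sample spikes to a channel vector.
add_artifacts <- function(x, fs, art) {
  n <- length(x)
  duration <- n / fs
  if (art$blink_rate > 0) {
    for (t0 in poisson_events(art$blink_rate, duration)) {
      w <- round(art$blink_width * fs)
      i0 <- floor(t0 * fs) + 1
      idx <- i0:min(n, i0 + w - 1)
      shape <- 0.5 * (1 - cos(2 * pi * seq_along(idx) / w))
      x[idx] <- x[idx] + art$blink_amplitude * shape
    }
  }
  if (art$spike_rate > 0) {
    for (t0 in poisson_events(art$spike_rate, duration)) {
      i0 <- min(n, floor(t0 * fs) + 1)
      x[i0] <- x[i0] + sample(c(-1, 1), 1) * art$spike_amplitude
    }
  }
  x
}

# Background noise for one channel: white + pink + optional alpha bursts.
channel_noise <- function(n, fs, noise) {
  x <- numeric(n)
  if (noise$white_sd > 0) x <- x + stats::rnorm(n, sd = noise$white_sd)
  if (noise$pink_sd > 0) x <- x + pink_noise(n, noise$pink_sd, noise$pink_exponent)
  if (noise$alpha_burst_rate > 0) {
    duration <- n / fs
    for (t0 in poisson_events(noise$alpha_burst_rate, duration)) {
      f <- stats::runif(1, 8, 12)
      width <- stats::runif(1, 0.5, 1.5)
      w <- round(width * fs)
      i0 <- floor(t0 * fs) + 1
      idx <- i0:min(n, i0 + w - 1)
      tt <- (seq_along(idx) - 1) / fs
      taper <- 0.5 * (1 - cos(2 * pi * tt / width))
      x[idx] <- x[idx] +
        noise$alpha_burst_amplitude * taper * sin(2 * pi * f * tt)
    }
  }
  x
}
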