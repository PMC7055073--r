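# Small simulation setups shared across tests.

# Compact session: short runs at a low rate, integer cycles per 2-s epoch.
small_config <- function(n_runs = 4, stim_duration = 8, fs = 128,
                         seed = 11, noise = noise_params(),
                         envelope = envelope_params(rise_tau = 1.5,
                                                    adapt_tau = 2,
                                                    peak_time = 4),
                         phase_jitter_sd = 0, ...) {
  ssep_sim_config(
    n_runs = n_runs, stim_duration = stim_duration, pre_stim = 0.5,
    post_stim = 0.5, fs = fs, stim_freq = 10,
    phase_jitter_sd = phase_jitter_sd,
    envelope = envelope, noise = noise, seed = seed, ...
  )
}

# Deterministic, noise-free, constant-amplitude response.
clean_config <- function(amplitude = 1e-6, n_runs = 3, stim_duration = 8,
                         fs = 128, seed = 1) {
  small_config(
    n_runs = n_runs, stim_duration = stim_duration, fs = fs, seed = seed,
    noise = noise_params(white_sd = 0, pink_sd = 0),
    envelope = envelope_piecewise(c(0, stim_duration),
                                  c(amplitude, amplitude))
  )
}

no_signal <- function() {
  envelope_piecewise(c(0, 1), c(0, 0))
}

# Single-channel sinusoidal test recording.
sine_recording <- function(freq = 10, amp = 1e-6, fs = 512, pre = 1,
                           dur = 8, post = 1, phase = 0) {
  n <- round((pre + dur + post) * fs)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  on <- t >= pre & t < pre + dur
  x[on] <- amp * sin(2 * pi * freq * (t[on] - pre) + phase)
  ssep_recording(x, fs = fs, stim_onset = pre, stim_duration = dur,
                 stim_freq = freq)
}
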