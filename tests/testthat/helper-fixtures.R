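# shared fixtures: tiny traces and pulses built in code

# a bare trace object from a signals matrix (defaults: 60 kHz)
make_trace <- function(signals, fs = 60000, segment_id = "seg1",
                       day_id = "day1") {
  structure(
    list(signals = signals, sample_rate_hz = fs,
         segment_id = segment_id, day_id = day_id),
    class = "bsfc_trace"
  )
}

# constant-baseline five-channel trace
flat_trace <- function(n = 1000, values = c(S405 = 1, S488 = 2, S633 = 3,
                                            FP1 = 0, FP2 = 0), ...) {
  m <- matrix(rep(values, each = n), nrow = n,
              dimnames = list(NULL, names(values)))
  make_trace(m, ...)
}

# unit gaussian pulse centred at `center` with FWHM in samples
gaussian_pulse <- function(n, center, fwhm, amplitude = 1) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  amplitude * exp(-0.5 * ((seq_len(n) - center) / s)^2)
}

# default physics chain used across tests
default_velocity <- function() flow_velocity(3, 900)

# small noise-free noise model
quiet_noise <- function(baseline = 0) {
  noise_model(
    baseline = c(S405 = baseline, S488 = baseline, S633 = baseline,
                 FP1 = 0, FP2 = 0),
    drift_amplitude = 0, sigma = c(S405 = 0, S488 = 0, S633 = 0,
                                   FP1 = 0, FP2 = 0)
  )
}
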