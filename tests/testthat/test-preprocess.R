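test_that("band-pass filter removes DC and passes in-band tones", {
  fs <- 60000
  spec <- filter_spec()

  # constant input is annihilated
  y <- bandpass_filter(rep(5, 20000), spec, fs = fs)
  expect_lt(max(abs(y)), 1e-6 * 5)

  # 1 kHz tone sits mid-band: amplitude preserved within 5%
  t <- seq_len(30000) / fs
  y1 <- bandpass_filter(sin(2 * pi * 1000 * t), spec, fs = fs)
  expect_lt(abs(max(abs(y1[5000:25000])) - 1), 0.05)

  # 20 kHz tone is far beyond the 6 kHz corner: strongly attenuated
  y2 <- bandpass_filter(sin(2 * pi * 20000 * t), spec, fs = fs)
  expect_lt(max(abs(y2[5000:25000])), 0.1)

  expect_error(bandpass_filter(rnorm(100), filter_spec(band = c(50, 4e4)),
                               fs = fs), "Nyquist")
  expect_error(filter_spec(band = c(6000, 50)))
})

test_that("zero-phase filtering preserves peak locations", {
  fs <- 60000
  n <- 60000
  x <- gaussian_pulse(n, 30000, 25, amplitude = 10)
  y <- bandpass_filter(x, filter_spec(), fs = fs)
  expect_lte(abs(which.max(y) - 30000), 1)
})

test_that("normalization factor implements the spectralon formula", {
  expect_equal(normalization_factor(calibration_record(405, 2, 0.2, 0.5)),
               5)
  # equal powers: factor reduces to the spectralon intensity
  expect_equal(normalization_factor(calibration_record(488, 1.3, 1.3, 7)),
               7)
  # OD = 1.0 neutral density -> power ratio 10
  expect_equal(normalization_factor(calibration_record(633, 10, 1, 1)),
               10)
  expect_error(calibration_record(633, 1, 0, 1), "> 0")
  expect_error(calibration_record(550, 1, 1, 1), "wavelength")
})

test_that("applying normalization rescales scattering channels only", {
  tr <- flat_trace(values = c(S405 = 4, S488 = 6, S633 = 8, FP1 = 2,
                              FP2 = 1))
  # unit factors are the identity
  id <- apply_normalization(tr, c(S405 = 1, S488 = 1, S633 = 1))
  expect_identical(id$signals, tr$signals)
  # scaling a channel by c and normalizing by c recovers the original
  tr2 <- tr
  tr2$signals[, "S405"] <- tr$signals[, "S405"] * 3
  rec <- apply_normalization(tr2, c(S405 = 3, S488 = 1, S633 = 1))
  expect_equal(rec$signals, tr$signals)
  # fluorescence untouched
  f <- apply_normalization(tr, c(S405 = 2, S488 = 2, S633 = 2))
  expect_identical(f$signals[, "FP1"], tr$signals[, "FP1"])
  expect_error(apply_normalization(tr, c(S405 = 1, S488 = 1)), "missing")
})

test_that("two days differing only by power normalize identically", {
  cfg <- acquisition_config(segment_duration_s = 0.2)
  ev <- event_spec("NC", 0.1, 20, c(S405 = 5, S488 = 4, S633 = 3))
  base <- render_trace(list(ev), quiet_noise(1), cfg, seed = 1)$trace
  powers <- c(S405 = 1.7, S488 = 0.8, S633 = 1.2)
  day2 <- base
  for (ch in names(powers)) {
    day2$signals[, ch] <- base$signals[, ch] * powers[[ch]]
  }
  n1 <- apply_normalization(base, c(S405 = 1, S488 = 1, S633 = 1))
  n2 <- apply_normalization(day2, powers)
  expect_equal(n1$signals, n2$signals, tolerance = 1e-12)
})

test_that("cumulative scatter is the exact pointwise channel sum", {
  tr <- flat_trace(n = 50)
  expect_true(all(cumulative_scatter(tr) == 6))
  tr$signals[, "S488"] <- 0
  expect_true(all(cumulative_scatter(tr) == 4))
  # pulse linearity: co-located unit pulses sum to 3x one channel
  n <- 2000
  p <- gaussian_pulse(n, 1000, 24)
  m <- matrix(0, n, 5, dimnames = list(NULL, c("S405", "S488", "S633",
                                               "FP1", "FP2")))
  for (ch in c("S405", "S488", "S633")) m[, ch] <- p
  expect_equal(max(cumulative_scatter(make_trace(m))), 3 * max(p))
  # exactness at every sample
  rand <- matrix(rnorm(5 * 100), 100, 5,
                 dimnames = list(NULL, colnames(m)))
  tr2 <- make_trace(rand)
  expect_identical(cumulative_scatter(tr2), rowSums(rand[, 1:3]))
})

test_that("filtering and normalization commute (both linear)", {
  cfg <- acquisition_config(segment_duration_s = 0.2)
  ev <- event_spec("NC", 0.1, 22, c(S405 = 6, S488 = 5, S633 = 4))
  tr <- render_trace(list(ev), noise_model(), cfg, seed = 8)$trace
  f <- c(S405 = 2.2, S488 = 0.7, S633 = 1.4)
  a <- apply_normalization(bandpass_filter(tr), f)
  b <- bandpass_filter(apply_normalization(tr, f))
  expect_lt(max(abs(a$signals - b$signals)), 1e-9)
})

test_that("summing channels improves pulse SNR over single channels", {
  cfg <- acquisition_config(segment_duration_s = 0.2)
  ev <- event_spec("NC", 0.1, 20, c(S405 = 6, S488 = 6, S633 = 6))
  snr <- function(x) {
    quiet <- x[1:3000]
    (max(x) - mean(quiet)) / stats::sd(quiet)
  }
  wins <- vapply(1:8, function(s) {
    tr <- render_trace(list(ev), noise_model(drift_amplitude = 0), cfg,
                       seed = 100 + s)$trace
    cum_snr <- snr(cumulative_scatter(tr))
    single <- vapply(c("S405", "S488", "S633"),
                     function(ch) snr(tr$signals[, ch]), numeric(1))
    cum_snr >= max(single)
  }, logical(1))
  # independent channel noise: the sqrt(3) gain should win essentially
  # every seeded replicate
  expect_gte(mean(wins), 7 / 8)
})
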