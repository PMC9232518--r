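test_that("cluster size draws follow the category distribution", {
  # degenerate distribution is deterministic
  d1 <- cluster_size_distribution(1, 0, 0, 0, 0)
  expect_true(all(sample_cluster_size(d1, 50, seed = 1) == 1L))

  # fraction of singles within 3 sigma (binomial) of the nominal rate
  dd <- cluster_size_distribution()
  n <- 1e5
  draws <- sample_cluster_size(dd, n, seed = 42)
  p <- 0.658
  expect_lt(abs(mean(draws == 1) - p), 3 * sqrt(p * (1 - p) / n))

  # within-category draws are uniform: mean of U{3..6} is 4.5
  d36 <- cluster_size_distribution(0, 0, 1, 0, 0)
  m <- mean(sample_cluster_size(d36, 1e4, seed = 7))
  expect_equal(m, 4.5, tolerance = 0.05)

  expect_error(cluster_size_distribution(0.5, 0.5, 0.1, 0, 0), "sum")
})

test_that("event pulses have the transit-physics FWHM", {
  cfg <- acquisition_config(segment_duration_s = 1)
  # 15 um object + 5 um slit at defaults -> ~21.6 points
  ev <- event_spec("CTC", 0.5, 15,
                   c(S405 = 1, S488 = 1, S633 = 1, FP1 = 1))
  p <- event_pulse(ev, cfg)
  expect_gte(p$fwhm_points, 21)
  expect_lte(p$fwhm_points, 22)
  # 17.2 um cluster-scale object -> ~24 points
  ev2 <- event_spec("NC", 0.5, 17.2, c(S633 = 1))
  expect_equal(event_pulse(ev2, cfg)$fwhm_points, 24, tolerance = 0.05)
  # gaussian shape: measured FWHM of the rendered snippet matches spec
  vals <- p$channels$S405$values
  above <- sum(vals > max(vals) / 2)
  expect_lte(abs(above - round(p$fwhm_points)), 1)
  # zero-amplitude channels are absent (flat zero contribution)
  expect_null(event_pulse(ev2, cfg)$channels$S405)
})

test_that("event spec enforces the class taxonomy", {
  expect_error(event_spec("CTCC", 0.5, 20, c(S405 = 1, FP1 = 1),
                          n_cells = 1), "n_cells")
  expect_error(event_spec("GFP_ONLY", 0.5, 10, c(S405 = 1, FP1 = 1)),
               "zero scattering")
  expect_error(event_spec("NC", 0.5, 20, c(S405 = 1, FP1 = 2)),
               "FP1")
  expect_error(event_spec("CTC", 0.5, 12, c(S405 = 1)), "FP1")
})

test_that("rendering is seeded, truth-complete and superposes pulses", {
  cfg <- acquisition_config(segment_duration_s = 0.5)
  nm <- quiet_noise(baseline = 2)

  # zero events, zero noise -> constant baseline, empty truth
  r0 <- render_trace(list(), nm, cfg, seed = 1)
  expect_identical(nrow(r0$truth), 0L)
  expect_true(all(r0$trace$signals[, "S405"] == 2))

  # one CTCC event: one truth row, FP1 and scattering co-located
  ev <- event_spec("CTCC", 0.25, 20,
                   c(S405 = 5, S488 = 3, S633 = 2.5, FP1 = 6),
                   n_cells = 3)
  r1 <- render_trace(list(ev), nm, cfg, seed = 2)
  expect_identical(nrow(r1$truth), 1L)
  expect_identical(r1$truth$center_sample,
                   which.max(r1$trace$signals[, "FP1"]))
  expect_identical(which.max(r1$trace$signals[, "S405"]),
                   which.max(r1$trace$signals[, "FP1"]))

  # determinism: same seed bit-identical, different seed differs
  noisy <- noise_model()
  evs <- lapply(seq(0.05, 0.45, length.out = 20), function(ct) {
    event_spec("NC", ct, 20, c(S405 = 8, S488 = 8, S633 = 8))
  })
  ra <- render_trace(evs, noisy, cfg, seed = 11)
  rb <- render_trace(evs, noisy, cfg, seed = 11)
  rc <- render_trace(evs, noisy, cfg, seed = 12)
  expect_identical(ra$trace$signals, rb$trace$signals)
  expect_false(identical(ra$trace$signals, rc$trace$signals))
  expect_identical(nrow(ra$truth), 20L)
})

test_that("ground-truth row count always equals requested event count", {
  cfg <- acquisition_config(segment_duration_s = 0.5)
  for (s in 1:3) {
    n_ev <- 5L * s
    evs <- lapply(seq_len(n_ev), function(i) {
      event_spec("NC", 0.5 * i / (n_ev + 1), 20, c(S633 = 4))
    })
    r <- render_trace(evs, noise_model(), cfg, seed = s)
    expect_identical(nrow(r$truth), n_ev)
  }
})

test_that("blood background scale strictly decreases scattering SNR", {
  cfg <- acquisition_config(segment_duration_s = 0.2)
  ev <- event_spec("NC", 0.1, 20, c(S405 = 8, S488 = 8, S633 = 8))
  snr <- vapply(c(1, 2, 4), function(scale) {
    nm <- noise_model(drift_amplitude = 0, blood_background_scale = scale)
    r <- render_trace(list(ev), nm, cfg, seed = 99)
    x <- r$trace$signals[, "S405"]
    quiet <- x[1:3000] # event-free region
    (max(x) - mean(quiet)) / stats::sd(quiet)
  }, numeric(1))
  expect_true(all(diff(snr) < 0))
})

test_that("simulated days expose calibration and class mix", {
  cfg <- acquisition_config(segment_duration_s = 2)
  d <- simulate_day("dayX", cfg, noise_model(), seed = 5,
                    n_clusters = 6, n_singles = 2, n_nc = 20,
                    n_segments = 2)
  expect_length(d$segments, 2)
  expect_identical(sum(d$truth$kind == "CTCC"), 6L)
  expect_identical(sum(d$truth$kind == "CTC"), 2L)
  expect_identical(sum(d$truth$kind == "NC"), 20L)
  expect_true(all(d$truth$n_cells[d$truth$kind == "CTCC"] >= 3))
  expect_identical(d$calibration$wavelength_nm, c(405, 488, 633))
  # same seed reproduces bit-identically
  d2 <- simulate_day("dayX", cfg, noise_model(), seed = 5,
                     n_clusters = 6, n_singles = 2, n_nc = 20,
                     n_segments = 2)
  expect_identical(d$segments[[1]]$signals, d2$segments[[1]]$signals)
  expect_identical(d$truth, d2$truth)
})

test_that("trace CSV round-trips through gzip", {
  cfg <- acquisition_config(segment_duration_s = 0.01)
  r <- render_trace(list(), noise_model(), cfg, seed = 3)
  path <- file.path(tempdir(), "trace.csv.gz")
  write_trace_csv(r$trace, path)
  back <- read_trace_csv(path, cfg)
  expect_equal(back$signals, r$trace$signals, tolerance = 1e-12)
  unlink(path)
})
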