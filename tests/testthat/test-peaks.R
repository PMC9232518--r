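test_that("segment threshold is mean + k * sd of the whole trace", {
  expect_equal(segment_threshold(rep(4, 100)), 4)
  set.seed(123)
  x <- rnorm(1e6)
  expect_equal(segment_threshold(x), 3, tolerance = 0.01)
  # homogeneity for mean-zero input
  expect_equal(segment_threshold(5 * x), 5 * segment_threshold(x),
               tolerance = 1e-9)
  expect_error(segment_threshold(1), "length")
})

test_that("candidate maxima are strict local maxima, plateaus leftmost", {
  expect_identical(find_candidate_maxima(1:10), integer(0))
  # single noise-free pulse peaks exactly at its center
  p <- gaussian_pulse(501, 251, 24)
  expect_identical(find_candidate_maxima(p), 251L)
  # two-sample plateau at the maximum resolves to the left index
  expect_identical(find_candidate_maxima(c(0, 1, 2, 2, 1, 0)), 3L)
  expect_identical(find_candidate_maxima(c(0, 3, 0, 5, 5, 5, 0, 2, 0)),
                   c(2L, 4L, 8L))
})

test_that("threshold crossings define disjoint sorted ranges", {
  expect_identical(nrow(define_ranges(rep(0, 100), 1)), 0L)
  p <- gaussian_pulse(1000, 500, 30)
  r <- define_ranges(p, 0.5)
  expect_identical(nrow(r), 1L)
  expect_true(r$start <= 500 && 500 < r$end)
  # two separated pulses -> two ranges
  x <- gaussian_pulse(2000, 500, 30) + gaussian_pulse(2000, 1500, 30)
  r2 <- define_ranges(x, 0.5)
  expect_identical(nrow(r2), 2L)
  expect_true(all(r2$end[-nrow(r2)] <= r2$start[-1]))
})

test_that("deduplication keeps one tallest peak per range", {
  # two local maxima in one range: the taller survives
  x <- c(rep(0, 10), 2, 1.5, 3, rep(0, 10))
  thr <- 1
  pk <- deduplicate(find_candidate_maxima(x), define_ranges(x, thr), x)
  expect_identical(nrow(pk), 1L)
  expect_identical(pk$location, 13L)
  expect_identical(pk$height, 3)
  # tie in height: leftmost survives
  x2 <- c(rep(0, 5), 2, 1.5, 2, rep(0, 5))
  pk2 <- deduplicate(find_candidate_maxima(x2), define_ranges(x2, 1), x2)
  expect_identical(pk2$location, 6L)
  # sub-threshold candidates outside all ranges are removed
  x3 <- c(rep(0, 5), 0.5, rep(0, 5), 3, rep(0, 5))
  pk3 <- deduplicate(find_candidate_maxima(x3), define_ranges(x3, 1), x3)
  expect_identical(pk3$location, 12L)
})

test_that("FWHM and AUC characterize peaks correctly", {
  # noise-free gaussian with sigma = 10 samples -> FWHM 23.55
  n <- 2001
  x <- exp(-0.5 * ((seq_len(n) - 1001) / 10)^2)
  pk <- deduplicate(find_candidate_maxima(x),
                    define_ranges(x, segment_threshold(x)), x)
  pk <- peak_characteristics(pk, x)
  expect_equal(pk$fwhm_points, 2 * sqrt(2 * log(2)) * 10,
               tolerance = 0.5 / 23.55)
  # rectangular pulse of width w -> FWHM = w +/- 1 (plateau maxima
  # resolve to the plateau start)
  w <- 40
  xr <- c(rep(0, 500), rep(1, w), rep(0, 500))
  expect_identical(find_candidate_maxima(xr), 501L)
  pkr <- data.frame(location = 501L, height = 1,
                    range_start = 501L, range_end = 501L + w)
  pkr <- peak_characteristics(pkr, xr)
  expect_lte(abs(pkr$fwhm_points - w), 1)
  # amplitude doubling leaves FWHM unchanged
  pk2 <- peak_characteristics(
    data.frame(location = 1001L, height = 2, range_start = 900L,
               range_end = 1100L), 2 * x)
  expect_equal(pk2$fwhm_points, pk$fwhm_points, tolerance = 1e-6)
  # AUC sums signal minus baseline over the range
  flat <- c(rep(1, 10), rep(3, 5), rep(1, 10))
  pk3 <- peak_characteristics(
    data.frame(location = 12L, height = 3, range_start = 11L,
               range_end = 16L), flat)
  expect_equal(pk3$auc, 5 * (3 - mean(flat)))
})

test_that("width gate retains exactly the >= 20 point peaks", {
  pk <- data.frame(fwhm_points = c(19.9, 20, 24, 11))
  expect_identical(width_gate(pk)$fwhm_points, c(20, 24))
  expect_identical(nrow(width_gate(pk[0, , drop = FALSE])), 0L)
})

test_that("detector recovers injected supra-threshold events exactly", {
  # noise-free traces: detected locations within +/-1 sample of truth,
  # FWHM within 1 point, count equal to injected count
  cfg <- acquisition_config(segment_duration_s = 1)
  centers <- seq(0.1, 0.9, length.out = 9)
  evs <- lapply(seq_along(centers), function(i) {
    d <- c(12, 15, 17.2, 20, 22, 25, 28, 30, 33)[i]
    event_spec("NC", centers[i], d, c(S405 = 5, S488 = 4, S633 = 3))
  })
  r <- render_trace(evs, quiet_noise(), cfg, seed = 1)
  cum <- cumulative_scatter(r$trace)
  # noise-free signal: threshold from the quiet parts is ~0; use a tiny
  # fraction of the max as the supra-threshold criterion
  pk <- detect_peaks(r$trace, "CUMULATIVE", edge_exclude = 1000)
  expect_identical(nrow(pk), length(evs))
  ord <- order(pk$location)
  expect_true(all(abs(pk$location[ord] - r$truth$center_sample) <= 1))
  expect_true(all(abs(pk$fwhm_points[ord] - r$truth$fwhm_points) <= 1))
})

test_that("every retained peak exceeds its segment threshold", {
  cfg <- acquisition_config(segment_duration_s = 0.5)
  d <- simulate_day("d", cfg, noise_model(), seed = 31, n_clusters = 5,
                    n_singles = 2, n_nc = 30, n_segments = 1)
  filt <- bandpass_filter(d$segments[[1]])
  pk <- detect_peaks(filt, "CUMULATIVE")
  thr <- attr(pk, "threshold")
  expect_true(all(pk$height > thr))
  # ranges pairwise disjoint, one peak per range
  expect_identical(anyDuplicated(pk$range_start), 0L)
  o <- order(pk$range_start)
  expect_true(all(pk$range_end[o][-nrow(pk)] <= pk$range_start[o][-1]))
})

test_that("pure-noise peak counts fall as the threshold rises", {
  set.seed(77)
  x <- rnorm(2e5)
  counts <- vapply(c(3, 4, 5), function(k) {
    nrow(deduplicate(find_candidate_maxima(x),
                     define_ranges(x, segment_threshold(x, k)), x))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_lt(counts[3], counts[1])
})
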