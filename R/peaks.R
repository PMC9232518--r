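# Peak detection on the cumulative-scatter and FP1 signals: a 3-sigma
# whole-segment threshold defines peak ranges, candidate local maxima are
# deduplicated to one peak per range, and each peak is characterized by
# location, height, interpolated FWHM, and area under the curve. A
# physics-derived minimum-width gate then separates cluster candidates
# from single-cell events.

#' Whole-segment intensity threshold
#'
#' mean(signal) + k * sd(signal) over the entire segment (default
#' k = 3). After band-pass filtering the mean is ~0, so this reduces to a
#' 3-sigma threshold while staying well defined for unfiltered inputs.
#'
#' @param signal numeric vector.
#' @param sigma_mult threshold multiplier k.
#' @return scalar threshold.
#' @export
segment_threshold <- function(signal, sigma_mult = 3) {
  if (length(signal) < 2) stop_bsfc("signal must have length >= 2")
  mean(signal) + sigma_mult * stats::sd(signal)
}

#' All strict local maxima of a signal
#'
#' A sample is a candidate if it exceeds both neighbors; plateaus at a
#' local maximum are resolved to their leftmost index. Endpoints are
#' never maxima.
#'
#' @param signal numeric vector.
#' @return integer vector of locations (possibly empty).
#' @export
find_candidate_maxima <- function(signal) {
  r <- rle(signal)
  k <- length(r$values)
  if (k < 3) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-k]))
  i <- 2:(k - 1)
  is_max <- r$values[i] > r$values[i - 1] & r$values[i] > r$values[i + 1]
  starts[i][is_max]
}

#' Supra-threshold ranges of a signal
#'
#' Maximal runs of consecutive samples strictly above the threshold,
#' returned as half-open intervals `[start, end)`, disjoint and sorted.
#'
#' @param signal numeric vector.
#' @param threshold scalar threshold.
#' @return data.frame with integer columns `start`, `end`.
#' @export
define_ranges <- function(signal, threshold) {
  above <- signal > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = as.integer(starts[keep]),
             end = as.integer(ends[keep] + 1L))
}

#' One peak per range: deduplicate candidate maxima
#'
#' Assigns each candidate maximum to the supra-threshold range containing
#' it; candidates outside every range (i.e. below threshold) are
#' discarded, and within each range only the tallest candidate survives
#' (ties broken to the leftmost).
#'
#' @param candidates integer locations from [find_candidate_maxima()].
#' @param ranges data.frame from [define_ranges()].
#' @param signal the numeric signal both were computed from.
#' @return data.frame with columns `location`, `height`, `range_start`,
#'   `range_end` — one row per occupied range, sorted by location.
#' @export
deduplicate <- function(candidates, ranges, signal) {
  empty <- data.frame(location = integer(0), height = numeric(0),
                      range_start = integer(0), range_end = integer(0))
  if (length(candidates) == 0 || nrow(ranges) == 0) return(empty)
  candidates <- sort(candidates)
  idx <- findInterval(candidates, ranges$start)
  inside <- idx >= 1 & candidates < ranges$end[pmax(idx, 1)]
  candidates <- candidates[inside]
  idx <- idx[inside]
  if (length(candidates) == 0) return(empty)
  h <- signal[candidates]
  # per range: tallest candidate, leftmost on ties (order is by location)
  best <- tapply(seq_along(candidates), idx, function(ii) {
    ii[which.max(h[ii])]
  })
  sel <- sort(unname(unlist(best)))
  data.frame(location = candidates[sel], height = h[sel],
             range_start = ranges$start[idx[sel]],
             range_end = ranges$end[idx[sel]])
}

# interpolated FWHM around `location`, measured above the segment mean
# baseline; falls back to the range width when the half-max level does
# not rise above the baseline.
fwhm_interp <- function(signal, location, height, baseline,
                        range_start, range_end) {
  half <- (height + baseline) / 2
  if (half <= baseline) return(as.numeric(range_end - range_start))
  n <- length(signal)
  # walk left to the first sample below the half level
  l <- location
  while (l > 1 && signal[l - 1] > half) l <- l - 1
  left <- if (l == 1) 1 else {
    (l - 1) + (half - signal[l - 1]) / (signal[l] - signal[l - 1])
  }
  r <- location
  while (r < n && signal[r + 1] > half) r <- r + 1
  right <- if (r == n) n else {
    r + (signal[r] - half) / (signal[r] - signal[r + 1])
  }
  right - left
}

#' Complete peak characteristics
#'
#' For each deduplicated peak computes the FWHM in points (width of the
#' region above (height + baseline)/2, linearly interpolated at the
#' crossings, with the segment mean as baseline) and the AUC (sum of
#' signal minus baseline over the threshold-crossing range).
#'
#' @param peaks data.frame from [deduplicate()].
#' @param signal the signal the peaks were detected in.
#' @return `peaks` with columns `fwhm_points` and `auc` added.
#' @export
peak_characteristics <- function(peaks, signal) {
  baseline <- mean(signal)
  n <- nrow(peaks)
  fw <- numeric(n)
  auc <- numeric(n)
  for (i in seq_len(n)) {
    fw[i] <- fwhm_interp(signal, peaks$location[i], peaks$height[i],
                         baseline, peaks$range_start[i], peaks$range_end[i])
    idx <- peaks$range_start[i]:(peaks$range_end[i] - 1L)
    auc[i] <- sum(signal[idx] - baseline)
  }
  peaks$fwhm_points <- fw
  peaks$auc <- auc
  peaks
}

#' Detect peaks in one signal of a trace segment
#'
#' Runs the full chain: whole-segment threshold, candidate maxima,
#' supra-threshold ranges, one-peak-per-range deduplication, and peak
#' characteristics. Peaks within `edge_exclude` samples of either segment
#' edge are dropped (filter start-up transients live there). When a
#' `bsfc_trace` is supplied, per-channel intensities at each peak
#' location are recorded as columns `i405 ... iFP2`.
#'
#' @param x numeric signal, or a `bsfc_trace` together with `channel`.
#' @param channel for trace input: `"CUMULATIVE"` (sum of scattering
#'   channels) or `"FP1"`.
#' @param sigma_mult threshold multiplier (default 3; 5 is also offered
#'   for the fluorescence channel).
#' @param edge_exclude samples excluded at each segment edge.
#' @return data.frame of peaks with columns `channel_source`, `location`,
#'   `height`, `range_start`, `range_end`, `fwhm_points`, `auc` (and
#'   per-channel intensities for trace input), plus attribute
#'   `"threshold"`.
#' @export
detect_peaks <- function(x, channel = c("CUMULATIVE", "FP1"),
                         sigma_mult = 3, edge_exclude = 1000) {
  channel <- match.arg(channel)
  trace <- NULL
  if (inherits(x, "bsfc_trace")) {
    trace <- x
    sig <- if (channel == "CUMULATIVE") cumulative_scatter(x)
           else x$signals[, "FP1"]
  } else {
    sig <- x
  }
  thr <- segment_threshold(sig, sigma_mult)
  cand <- find_candidate_maxima(sig)
  rng <- define_ranges(sig, thr)
  pk <- deduplicate(cand, rng, sig)
  if (nrow(pk) > 0 && edge_exclude > 0) {
    n <- length(sig)
    pk <- pk[pk$location > edge_exclude & pk$location <= n - edge_exclude, ,
             drop = FALSE]
  }
  pk <- peak_characteristics(pk, sig)
  pk <- cbind(channel_source = rep(channel, nrow(pk)), pk)
  if (!is.null(trace) && nrow(pk) > 0) {
    ints <- trace$signals[pk$location, , drop = FALSE]
    colnames(ints) <- sub("^S", "i", colnames(ints))
    colnames(ints) <- sub("^FP", "iFP", colnames(ints))
    pk <- cbind(pk, as.data.frame(ints))
    pk$segment_id <- trace$segment_id
    pk$day_id <- trace$day_id
  }
  rownames(pk) <- NULL
  attr(pk, "threshold") <- thr
  pk
}

#' Minimum-width gate for cluster candidates
#'
#' Retains peaks whose FWHM is at least `min_width` points (default 20,
#' the width of the largest expected single cell or white blood cell
#' under the transit physics); narrower peaks are removed as probable
#' single-cell events.
#'
#' @param peaks data.frame with a `fwhm_points` column.
#' @param min_width minimum FWHM in points.
#' @return the retained rows of `peaks`.
#' @export
width_gate <- function(peaks, min_width = 20) {
  peaks[peaks$fwhm_points >= min_width, , drop = FALSE]
}
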