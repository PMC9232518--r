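# Segment normalization and windowed feature extraction. Each 1.5-min
# segment is normalized per channel by one of four methods, then a fixed
# window of +/- 13 points around each event center is concatenated across
# the chosen scattering channels into one feature vector (81 values for
# all three channels).

#' Segment normalization methods
#'
#' @return character vector of the four supported methods.
#' @export
normalization_methods <- function() {
  c("MAX_PEAK", "MEAN_PEAK_5SIGMA", "ZERO_MEAN", "ZERO_MEDIAN")
}

#' Normalize a trace segment per channel
#'
#' * `MAX_PEAK`: divide by the height of the tallest detected peak in
#'   that channel (3-sigma detection within the channel).
#' * `MEAN_PEAK_5SIGMA`: divide by the mean height of detected peaks
#'   exceeding mean + 5 sd of the channel.
#' * `ZERO_MEAN`: (x - mean) / sd — independent of illumination power
#'   (invariant to channel gain and offset).
#' * `ZERO_MEDIAN`: (x - median) / sd.
#'
#' Statistics are computed per channel over the whole segment, peaks
#' included. The two peak-based methods are applied to the scattering
#' channels only (fluorescence channels carry no scattering peaks and are
#' never featurized); the moment-based methods standardize every channel.
#'
#' @param trace a `bsfc_trace`.
#' @param method one of [normalization_methods()].
#' @param edge_exclude edge margin passed to peak detection for the two
#'   peak-based methods.
#' @return the normalized trace.
#' @export
normalize_segment <- function(trace, method = "ZERO_MEAN",
                              edge_exclude = 1000) {
  stopifnot(inherits(trace, "bsfc_trace"))
  method <- match.arg(method, normalization_methods())
  out <- trace
  norm_channels <- if (method %in% c("MAX_PEAK", "MEAN_PEAK_5SIGMA")) {
    intersect(colnames(trace$signals), scatter_channels())
  } else {
    colnames(trace$signals)
  }
  for (ch in norm_channels) {
    x <- trace$signals[, ch]
    out$signals[, ch] <- switch(
      method,
      ZERO_MEAN = {
        s <- stats::sd(x)
        if (s == 0) stop_bsfc("zero sd in channel %s of segment %s/%s",
                              ch, trace$day_id, trace$segment_id)
        (x - mean(x)) / s
      },
      ZERO_MEDIAN = {
        s <- stats::sd(x)
        if (s == 0) stop_bsfc("zero sd in channel %s of segment %s/%s",
                              ch, trace$day_id, trace$segment_id)
        (x - stats::median(x)) / s
      },
      MAX_PEAK = {
        pk <- detect_peaks(x, sigma_mult = 3, edge_exclude = edge_exclude)
        if (nrow(pk) == 0) {
          stop_bsfc("no peaks for MAX_PEAK in channel %s of segment %s/%s",
                    ch, trace$day_id, trace$segment_id)
        }
        x / max(pk$height)
      },
      MEAN_PEAK_5SIGMA = {
        pk <- detect_peaks(x, sigma_mult = 5, edge_exclude = edge_exclude)
        if (nrow(pk) == 0) {
          stop_bsfc(
            "no peaks above 5 sigma in channel %s of segment %s/%s",
            ch, trace$day_id, trace$segment_id)
        }
        x / mean(pk$height)
      }
    )
  }
  out
}

#' Extract one windowed feature vector
#'
#' Takes `2 * half_window + 1` consecutive samples centered on the event
#' center from each requested scattering channel and concatenates them in
#' fixed channel order (405, 488, 633). The same center index is used for
#' every channel. Events whose window would cross a segment edge are
#' rejected (never padded).
#'
#' @param trace a (normalized) `bsfc_trace`.
#' @param center center sample index.
#' @param half_window half window width in samples (default 13).
#' @param channels scattering channels to include, in any order; the
#'   output always follows the canonical 405, 488, 633 order.
#' @return numeric vector of length `(2 * half_window + 1) * k`, or
#'   `NULL` (with a warning) if the window crosses a segment edge.
#' @export
extract_window <- function(trace, center, half_window = 13,
                           channels = scatter_channels()) {
  stopifnot(inherits(trace, "bsfc_trace"))
  channels <- intersect(scatter_channels(), channels) # canonical order
  if (length(channels) == 0) stop_bsfc("no valid scattering channels")
  n <- nrow(trace$signals)
  if (center <= half_window || center > n - half_window) {
    warning(sprintf("event at sample %d too close to segment edge; skipped",
                    center))
    return(NULL)
  }
  idx <- (center - half_window):(center + half_window)
  as.vector(trace$signals[idx, channels])
}

#' Assemble the feature matrix for labeled events
#'
#' Normalizes each referenced segment with `method`, extracts the
#' windowed feature vector for every labeled event, and stacks them into
#' a matrix. Rows follow a deterministic (day, segment, center) ordering;
#' events rejected by the edge rule are dropped.
#'
#' @param labeled_events data.frame with columns `day_id`, `segment_id`,
#'   `center_for_features`, `label` (and optionally `event_id`).
#' @param segments named list of `bsfc_trace` objects keyed by
#'   `"<day_id>/<segment_id>"` (raw or already normalized).
#' @param method normalization method; `NULL` if `segments` are already
#'   normalized.
#' @param channels scattering channels to include.
#' @param half_window half window width.
#' @return list with `X` (numeric matrix, one row per surviving event),
#'   `y` (character vector of labels), `day` (character vector), and
#'   `events` (the surviving rows of `labeled_events`).
#' @export
build_dataset <- function(labeled_events, segments, method = "ZERO_MEAN",
                          channels = scatter_channels(), half_window = 13) {
  channels <- intersect(scatter_channels(), channels)
  ncol_out <- (2 * half_window + 1) * length(channels)
  ord <- order(labeled_events$day_id, labeled_events$segment_id,
               labeled_events$center_for_features)
  labeled_events <- labeled_events[ord, , drop = FALSE]
  norm_cache <- list()
  rows <- vector("list", nrow(labeled_events))
  keep <- logical(nrow(labeled_events))
  for (i in seq_len(nrow(labeled_events))) {
    key <- paste(labeled_events$day_id[i], labeled_events$segment_id[i],
                 sep = "/")
    if (is.null(norm_cache[[key]])) {
      seg <- segments[[key]]
      if (is.null(seg)) stop_bsfc("no segment '%s' supplied", key)
      norm_cache[[key]] <- if (is.null(method)) seg
                           else normalize_segment(seg, method)
    }
    v <- extract_window(norm_cache[[key]],
                        labeled_events$center_for_features[i],
                        half_window, channels)
    if (!is.null(v)) {
      rows[[i]] <- v
      keep[i] <- TRUE
    }
  }
  X <- do.call(rbind, rows[keep])
  if (is.null(X)) X <- matrix(numeric(0), ncol = ncol_out)
  list(X = X, y = labeled_events$label[keep],
       day = labeled_events$day_id[keep],
       events = labeled_events[keep, , drop = FALSE])
}
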