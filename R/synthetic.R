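# Seeded synthetic five-channel trace generator. Emulates spiked
# whole-blood acquisitions: a scattering background with slow drift and
# white noise, tumor-cell / cluster transit pulses co-located across the
# scattering channels and the green-fluorescence (FP1) channel, scatter-only
# non-cluster (NC) events, and occasional fluorescence-only events with no
# scattering signature. Every event is recorded in a ground-truth table so
# the detector and classifier can be validated without any real data.

#' Cluster size distribution of a spiked sample
#'
#' Probabilities over the five size categories observed when preparing
#' cell clusters by gentle trypsinization: single cells, 2-cell clusters,
#' 3-6, 7-9 and >9 cell clusters. Defaults are the mean observed
#' distribution (65.8% singles, 17.1% 2-cell, 15.0% 3-6, 1.4% 7-9,
#' 0.7% >9).
#'
#' @param p_single,p_two,p_three_six,p_seven_nine,p_over_nine category
#'   probabilities; must be non-negative and sum to 1 within 1e-9.
#' @return object of class `bsfc_cluster_dist`.
#' @export
cluster_size_distribution <- function(p_single = 0.658, p_two = 0.171,
                                      p_three_six = 0.150,
                                      p_seven_nine = 0.014,
                                      p_over_nine = 0.007) {
  p <- c(single = p_single, two = p_two, three_six = p_three_six,
         seven_nine = p_seven_nine, over_nine = p_over_nine)
  if (any(p < 0)) stop_bsfc("cluster size probabilities must be >= 0")
  if (abs(sum(p) - 1) > 1e-9) {
    stop_bsfc("cluster size probabilities sum to %.10f, not 1", sum(p))
  }
  structure(list(probs = p), class = "bsfc_cluster_dist")
}

#' Draw cluster sizes (number of cells per event)
#'
#' Draws a size category according to the distribution, then a cell count
#' uniformly within the category (3-6 -> uniform on 3..6; 7-9 -> uniform
#' on 7..9; >9 -> uniform on 10..15).
#'
#' @param dist a [cluster_size_distribution()].
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return integer vector of cell counts.
#' @export
#' @examples
#' sample_cluster_size(cluster_size_distribution(), n = 5, seed = 1)
sample_cluster_size <- function(dist, n = 1, seed = NULL) {
  stopifnot(inherits(dist, "bsfc_cluster_dist"))
  with_seed(seed, {
    cat_idx <- sample.int(5, n, replace = TRUE, prob = dist$probs)
    lo <- c(1, 2, 3, 7, 10)[cat_idx]
    hi <- c(1, 2, 6, 9, 15)[cat_idx]
    lo + floor(stats::runif(n) * (hi - lo + 1))
  })
}

#' Noise model for synthetic traces
#'
#' Per-channel baseline level, a slow sinusoidal baseline drift, white
#' Gaussian noise, and a multiplier on the scattering-channel noise that
#' represents the extra background scatter of whole blood relative to
#' growth media (`blood_background_scale`, >= 1).
#'
#' @param baseline named numeric baseline per channel.
#' @param drift_amplitude amplitude of the sinusoidal baseline drift.
#' @param drift_period_s drift period in seconds.
#' @param sigma named numeric white-noise standard deviation per channel.
#' @param blood_background_scale multiplier (>= 1) applied to the white
#'   noise of the three scattering channels.
#' @return object of class `bsfc_noise`.
#' @export
noise_model <- function(baseline = c(S405 = 10, S488 = 10, S633 = 10,
                                     FP1 = 1, FP2 = 1),
                        drift_amplitude = 0.5,
                        drift_period_s = 30,
                        sigma = c(S405 = 1, S488 = 1, S633 = 1,
                                  FP1 = 0.3, FP2 = 0.3),
                        blood_background_scale = 1) {
  ch <- bsfc_channels()
  if (!all(ch %in% names(baseline)) || !all(ch %in% names(sigma))) {
    stop_bsfc("baseline and sigma must name all five channels")
  }
  if (any(sigma < 0)) stop_bsfc("noise sigma must be >= 0")
  if (blood_background_scale < 1) {
    stop_bsfc("blood_background_scale must be >= 1")
  }
  structure(
    list(baseline = baseline[ch], drift_amplitude = drift_amplitude,
         drift_period_s = drift_period_s, sigma = sigma[ch],
         blood_background_scale = blood_background_scale),
    class = "bsfc_noise"
  )
}

#' Specify one synthetic event
#'
#' An event is a transit pulse with a kind (`CTC` single tumor cell,
#' `CTCC` tumor cell cluster, `NC` non-cluster scattering event,
#' `GFP_ONLY` fluorescence event with no scattering signature), a center
#' time, an object diameter that sets the pulse width through the transit
#' physics, per-channel amplitudes, and optional integer sample offsets
#' (jitter) of the scattering channels relative to the nominal center.
#'
#' @param kind one of `"CTC"`, `"CTCC"`, `"NC"`, `"GFP_ONLY"`.
#' @param center_time_s pulse center in seconds from segment start.
#' @param object_diameter_um object diameter in um (ignored for
#'   `GFP_ONLY`, which has no scattering pulse but still a fluorescence
#'   transit width).
#' @param amplitudes named numeric pulse amplitudes per channel; missing
#'   channels default to 0.
#' @param n_cells number of cells (`CTC` 1, `CTCC` >= 2; `NA` otherwise).
#' @param jitter named integer sample offsets for scattering channels.
#' @return object of class `bsfc_event`.
#' @export
event_spec <- function(kind, center_time_s, object_diameter_um,
                       amplitudes, n_cells = NA_integer_,
                       jitter = c(S405 = 0L, S488 = 0L, S633 = 0L)) {
  kind <- match.arg(kind, c("CTC", "CTCC", "NC", "GFP_ONLY"))
  amp <- stats::setNames(numeric(5), bsfc_channels())
  amp[names(amplitudes)] <- amplitudes
  sc <- scatter_channels()
  if (kind == "CTCC" && (is.na(n_cells) || n_cells < 2)) {
    stop_bsfc("CTCC events need n_cells >= 2")
  }
  if (kind == "CTC") n_cells <- 1L
  if (kind == "GFP_ONLY" && any(amp[sc] != 0)) {
    stop_bsfc("GFP_ONLY events must have zero scattering amplitudes")
  }
  if (kind %in% c("CTC", "CTCC") && amp["FP1"] <= 0) {
    stop_bsfc("%s events must have FP1 amplitude > 0", kind)
  }
  if (kind == "NC" && amp["FP1"] != 0) {
    stop_bsfc("NC events must have FP1 amplitude = 0")
  }
  jit <- stats::setNames(integer(3), sc)
  jit[names(jitter)] <- as.integer(jitter)
  structure(
    list(kind = kind, n_cells = as.integer(n_cells),
         center_time_s = center_time_s,
         object_diameter_um = object_diameter_um,
         amplitudes = amp, jitter = jit),
    class = "bsfc_event"
  )
}

#' Render the per-channel pulse of one event
#'
#' Pulse shape is Gaussian with sigma = FWHM/2.355, the simplest unimodal
#' form consistent with slit convolution; its FWHM in samples equals the
#' transit time (object diameter + slit width over plug-flow velocity)
#' times the sampling rate. Scattering channels are shifted by their
#' jitter offsets.
#'
#' @param spec a [event_spec()].
#' @param config an [acquisition_config()].
#' @return list with `fwhm_points` (real), `half_len`, and `channels`: a
#'   named list of `list(offsets, values)` pulse supports relative to the
#'   event center sample.
#' @export
event_pulse <- function(spec, config) {
  stopifnot(inherits(spec, "bsfc_event"), inherits(config, "bsfc_config"))
  v <- flow_velocity(config$flow_rate_ul_min, config$channel_area_um2)
  dt <- transit_time(spec$object_diameter_um, config$slit_width_um, v)
  fwhm <- dt * config$sample_rate_hz
  sig <- fwhm / (2 * sqrt(2 * log(2))) # 2.355
  half <- max(1L, as.integer(ceiling(4 * sig)))
  off <- seq.int(-half, half)
  shape <- exp(-0.5 * (off / sig)^2)
  channels <- list()
  for (ch in bsfc_channels()) {
    a <- spec$amplitudes[[ch]]
    if (a == 0) next
    j <- if (ch %in% scatter_channels()) spec$jitter[[ch]] else 0L
    channels[[ch]] <- list(offsets = off + j, values = a * shape)
  }
  list(fwhm_points = fwhm, half_len = half, channels = channels)
}

new_trace <- function(signals, config, segment_id = "seg1",
                      day_id = "day1") {
  structure(
    list(signals = signals, sample_rate_hz = config$sample_rate_hz,
         segment_id = segment_id, day_id = day_id),
    class = "bsfc_trace"
  )
}

#' @export
print.bsfc_trace <- function(x, ...) {
  cat(sprintf("<bsfc trace %s/%s: %d samples x %d channels @ %g Hz>\n",
              x$day_id, x$segment_id, nrow(x$signals), ncol(x$signals),
              x$sample_rate_hz))
  invisible(x)
}

#' Render a full trace segment with ground truth
#'
#' Sum of baseline, sinusoidal drift, white Gaussian noise and the
#' superposed event pulses, per channel. Bit-identical for identical
#' seeds. Returns both the trace and a ground-truth table with one row
#' per requested event.
#'
#' @param events list of [event_spec()] objects (centers must lie within
#'   the segment; events may overlap).
#' @param noise a [noise_model()].
#' @param config an [acquisition_config()].
#' @param seed integer seed for the noise and drift phase.
#' @param segment_id,day_id identifiers stamped on the trace and truth.
#' @return list with `trace` (a `bsfc_trace`) and `truth` (data.frame:
#'   event_id, kind, n_cells, center_sample, fwhm_points, one amplitude
#'   column per channel).
#' @export
render_trace <- function(events, noise, config, seed = NULL,
                         segment_id = "seg1", day_id = "day1") {
  stopifnot(inherits(noise, "bsfc_noise"), inherits(config, "bsfc_config"))
  n <- config$n_samples
  ch <- bsfc_channels()
  sc <- scatter_channels()
  sig <- with_seed(seed, {
    phase <- stats::runif(length(ch), 0, 2 * pi)
    t <- seq_len(n) / config$sample_rate_hz
    m <- matrix(0, nrow = n, ncol = length(ch), dimnames = list(NULL, ch))
    for (i in seq_along(ch)) {
      s <- noise$sigma[[ch[i]]]
      if (ch[i] %in% sc) s <- s * noise$blood_background_scale
      m[, i] <- noise$baseline[[ch[i]]] +
        noise$drift_amplitude * sin(2 * pi * t / noise$drift_period_s +
                                      phase[i]) +
        (if (s > 0) stats::rnorm(n, 0, s) else 0)
    }
    m
  })
  truth <- data.frame(
    event_id = character(0), kind = character(0), n_cells = integer(0),
    center_sample = integer(0), fwhm_points = numeric(0)
  )
  amp_mat <- matrix(numeric(0), ncol = 5, dimnames = list(NULL, ch))
  for (k in seq_along(events)) {
    ev <- events[[k]]
    center <- as.integer(round(ev$center_time_s * config$sample_rate_hz))
    if (center < 1 || center > n) {
      stop_bsfc("event %d center %d outside segment [1, %d]", k, center, n)
    }
    p <- event_pulse(ev, config)
    for (cname in names(p$channels)) {
      idx <- center + p$channels[[cname]]$offsets
      keep <- idx >= 1 & idx <= n
      sig[idx[keep], cname] <- sig[idx[keep], cname] +
        p$channels[[cname]]$values[keep]
    }
    truth <- rbind(truth, data.frame(
      event_id = sprintf("%s_%s_ev%03d", day_id, segment_id, k),
      kind = ev$kind, n_cells = ev$n_cells, center_sample = center,
      fwhm_points = p$fwhm_points
    ))
    amp_mat <- rbind(amp_mat, ev$amplitudes)
  }
  if (nrow(truth) > 0) {
    colnames(amp_mat) <- paste0("amp_", ch)
    truth <- cbind(truth, as.data.frame(amp_mat))
    truth$segment_id <- segment_id
    truth$day_id <- day_id
    rownames(truth) <- NULL
  }
  list(trace = new_trace(sig, config, segment_id, day_id), truth = truth)
}

# draw the object diameter for an event, given its kind and cell count.
# single cells: uniform 8-13 um. 2-cell clusters: orientation across the
# slit is ambiguous, so the presented length spans one to two cell
# diameters. larger clusters scale as n^(1/3) of the base cell diameter
# (compact aggregate). NC events mimic the cluster width range.
draw_object_diameter <- function(kind, n_cells, cell_diameter_um = 12) {
  switch(
    kind,
    CTC = stats::runif(1, 8, min(13, cell_diameter_um + 1)),
    CTCC = if (n_cells == 2) {
      stats::runif(1, cell_diameter_um, 2 * cell_diameter_um)
    } else {
      cell_diameter_um * n_cells^(1 / 3) * stats::runif(1, 0.95, 1.1)
    },
    NC = stats::runif(1, 17, 30),
    GFP_ONLY = stats::runif(1, 8, 13)
  )
}

# spectral amplitude ratios: tumor events scatter strongest at 405 nm
# (1 : 0.6 : 0.5 across 405:488:633); NC events are 633-dominant so the
# classes are separable but share the cumulative-signal amplitude scale.
tumor_ratio <- c(S405 = 1, S488 = 0.6, S633 = 0.5)
nc_ratio <- c(S405 = 0.5, S488 = 0.6, S633 = 1)

#' Simulate one experimental "day"
#'
#' Generates a day's worth of trace segments containing spiked cluster
#' events (cell count drawn from `cluster_dist` conditioned on >= 3 cells),
#' single tumor cells, scatter-only NC events, and fluorescence-only
#' events occurring at rate `gfp_only_rate` among tumor events. Each day
#' carries its own illumination power factor per scattering wavelength,
#' together with the matching calibration record, so that daily power
#' normalization can be exercised end to end.
#'
#' @param day_id day identifier.
#' @param config an [acquisition_config()].
#' @param noise a [noise_model()].
#' @param seed integer seed for the day.
#' @param n_clusters number of cluster (>= 3 cells) events.
#' @param n_singles number of single-cell tumor events.
#' @param n_nc number of non-cluster scattering events.
#' @param gfp_only_rate probability of a fluorescence-only event per
#'   tumor event.
#' @param n_segments number of trace segments the events are spread over.
#' @param cluster_dist a [cluster_size_distribution()].
#' @param cell_diameter_um base tumor cell diameter in um.
#' @param amplitude_scale peak amplitude of the 405-channel pulse of a
#'   single tumor cell, in signal units; cluster amplitudes scale with
#'   n_cells^(1/3).
#' @param fp1_amplitude GFP pulse amplitude for tumor events.
#' @param power_factors named numeric per-wavelength illumination power
#'   factors; `NULL` draws them uniformly in `[0.7, 1.3]`.
#' @param jitter_range max absolute per-channel sample jitter of
#'   scattering pulses.
#' @return list with `segments` (list of `bsfc_trace`), `truth`
#'   (data.frame over all segments), and `calibration` (data.frame of
#'   daily calibration records).
#' @export
simulate_day <- function(day_id, config, noise, seed,
                         n_clusters = 30, n_singles = 10, n_nc = 300,
                         gfp_only_rate = 0.05, n_segments = 2,
                         cluster_dist = cluster_size_distribution(),
                         cell_diameter_um = 12,
                         amplitude_scale = 8, fp1_amplitude = 12,
                         power_factors = NULL, jitter_range = 1L) {
  stopifnot(inherits(config, "bsfc_config"), inherits(noise, "bsfc_noise"))
  sc <- scatter_channels()
  with_seed(derive_seed(seed, 0), {
    if (is.null(power_factors)) {
      power_factors <- stats::setNames(stats::runif(3, 0.7, 1.3), sc)
    }
    n_gfp <- stats::rbinom(1, n_clusters + n_singles, gfp_only_rate)
    # cluster sizes: condition the spiked-sample distribution on >= 3 cells
    p <- cluster_size_distribution()$probs
    cond <- cluster_size_distribution(0, 0,
                                      p[["three_six"]] / sum(p[3:5]),
                                      p[["seven_nine"]] / sum(p[3:5]),
                                      p[["over_nine"]] / sum(p[3:5]))
    sizes <- sample_cluster_size(cond, n_clusters)
    kinds <- c(rep("CTCC", n_clusters), rep("CTC", n_singles),
               rep("NC", n_nc), rep("GFP_ONLY", n_gfp))
    n_cells <- c(sizes, rep(1L, n_singles),
                 rep(NA_integer_, n_nc + n_gfp))
    ord <- sample.int(length(kinds))
    kinds <- kinds[ord]; n_cells <- n_cells[ord]
    seg_of <- rep_len(seq_len(n_segments), length(kinds))

    segments <- vector("list", n_segments)
    truth <- NULL
    for (s in seq_len(n_segments)) {
      in_seg <- which(seg_of == s)
      m <- length(in_seg)
      # evenly spaced slots with jitter keep events resolvable and clear
      # of the filter-transient edges
      margin <- 2500 / config$sample_rate_hz
      usable <- config$segment_duration_s - 2 * margin
      slot <- usable / max(m, 1)
      centers <- margin + (seq_len(m) - 0.5) * slot +
        stats::runif(m, -0.3, 0.3) * slot
      events <- vector("list", m)
      for (i in seq_len(m)) {
        k <- kinds[in_seg[i]]
        nc_i <- n_cells[in_seg[i]]
        d <- draw_object_diameter(k, nc_i, cell_diameter_um)
        amp <- stats::setNames(numeric(5), bsfc_channels())
        if (k %in% c("CTC", "CTCC")) {
          scale_i <- amplitude_scale *
            (if (is.na(nc_i)) 1 else nc_i^(1 / 3)) *
            stats::runif(1, 0.85, 1.15)
          amp[sc] <- scale_i * tumor_ratio * power_factors
          amp["FP1"] <- fp1_amplitude * stats::runif(1, 0.85, 1.15)
        } else if (k == "NC") {
          scale_i <- amplitude_scale * stats::runif(1, 1.1, 1.9)
          amp[sc] <- scale_i * nc_ratio * power_factors
        } else {
          amp["FP1"] <- fp1_amplitude * stats::runif(1, 0.85, 1.15)
        }
        jit <- stats::setNames(
          sample.int(2L * jitter_range + 1L, 3, replace = TRUE) -
            jitter_range - 1L, sc)
        events[[i]] <- event_spec(k, centers[i], d, amp,
                                  n_cells = nc_i, jitter = jit)
      }
      # scattering baseline also scales with illumination power
      noise_s <- noise
      noise_s$baseline[sc] <- noise$baseline[sc] * power_factors
      noise_s$sigma[sc] <- noise$sigma[sc] * sqrt(power_factors)
      r <- render_trace(events, noise_s, config,
                        seed = derive_seed(seed, s),
                        segment_id = sprintf("seg%d", s), day_id = day_id)
      segments[[s]] <- r$trace
      truth <- rbind(truth, r$truth)
    }
    calibration <- data.frame(
      day_id = day_id, wavelength_nm = c(405, 488, 633),
      power_sample_mW = 1, power_spectralon_mW = 1,
      intensity_spectralon = as.numeric(power_factors)
    )
    list(segments = segments, truth = truth, calibration = calibration)
  })
}

#' Write a trace segment to CSV
#'
#' Columns: sample_index then one column per channel. Optionally gzipped
#' (by file extension `.gz`).
#'
#' @param trace a `bsfc_trace`.
#' @param path output path; a `.gz` suffix writes through a gzip
#'   connection.
#' @return the path, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(sample_index = seq_len(nrow(trace$signals)),
                   trace$signals, check.names = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a trace segment from CSV
#'
#' @param path CSV path as written by [write_trace_csv()].
#' @param config an [acquisition_config()] supplying the sampling rate.
#' @param segment_id,day_id identifiers for the restored trace.
#' @return a `bsfc_trace`.
#' @export
read_trace_csv <- function(path, config, segment_id = "seg1",
                           day_id = "day1") {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, bsfc_channels()])
  new_trace(m, config, segment_id, day_id)
}
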