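# End-to-end orchestration: simulate -> filter -> normalize -> detect ->
# gate -> label -> featurize -> train -> evaluate, with one master seed
# driving every stochastic stage and per-stage event counts logged so the
# detection funnel can be inspected.

#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end synthetic benchmark run.
#' Defaults describe the standard benchmark: 5 training days and 2 test
#' days of 10-second segments, ~30 cluster and ~300 non-cluster events
#' per day, a 50-model balanced cascade on zero-mean-normalized
#' three-channel feature vectors.
#'
#' @param seed master seed.
#' @param n_train_days,n_test_days number of simulated experiment days.
#' @param segments_per_day trace segments per day.
#' @param segment_duration_s segment length in seconds.
#' @param clusters_per_day,singles_per_day,nc_per_day event counts per
#'   day.
#' @param gfp_only_rate rate of fluorescence-only events among tumor
#'   events.
#' @param sigma_mult peak detection threshold multiplier.
#' @param min_width_points minimum FWHM gate in points.
#' @param method segment normalization method.
#' @param channels scattering channels used in feature vectors.
#' @param half_window feature half window in points.
#' @param hp a [boost_hyperparams()].
#' @param n_models cascade size.
#' @param noise a [noise_model()].
#' @param config an [acquisition_config()]; its segment duration is
#'   overridden by `segment_duration_s`.
#' @return object of class `bsfc_run_config`.
#' @export
pipeline_config <- function(seed = 1,
                            n_train_days = 5, n_test_days = 2,
                            segments_per_day = 2,
                            segment_duration_s = 10,
                            clusters_per_day = 30, singles_per_day = 10,
                            nc_per_day = 300, gfp_only_rate = 0.05,
                            sigma_mult = 3, min_width_points = 20,
                            method = "ZERO_MEAN",
                            channels = scatter_channels(),
                            half_window = 13,
                            hp = boost_hyperparams(), n_models = 50,
                            noise = noise_model(),
                            config = acquisition_config()) {
  config <- acquisition_config(
    sample_rate_hz = config$sample_rate_hz,
    segment_duration_s = segment_duration_s,
    flow_rate_ul_min = config$flow_rate_ul_min,
    channel_area_um2 = config$channel_area_um2,
    slit_width_um = config$slit_width_um
  )
  structure(
    list(seed = seed, n_train_days = n_train_days,
         n_test_days = n_test_days, segments_per_day = segments_per_day,
         clusters_per_day = clusters_per_day,
         singles_per_day = singles_per_day, nc_per_day = nc_per_day,
         gfp_only_rate = gfp_only_rate, sigma_mult = sigma_mult,
         min_width_points = min_width_points, method = method,
         channels = channels, half_window = half_window, hp = hp,
         n_models = n_models, noise = noise, config = config),
    class = "bsfc_run_config"
  )
}

#' Simulate, preprocess and featurize one experiment day
#'
#' Runs the per-day part of the pipeline: simulate the day's segments,
#' band-pass filter, apply the day's power normalization, detect peaks in
#' the cumulative-scatter and FP1 signals, gate by minimum width, label
#' by FP1 co-occurrence, and extract feature vectors. Traces are dropped
#' after featurization so memory stays bounded by the feature matrix.
#'
#' @param day_id day identifier.
#' @param run a [pipeline_config()].
#' @param day_seed seed for this day.
#' @return list with `X`, `y`, `day`, `truth`, `counts` (detection
#'   funnel: detected, gated, labeled_ctcc, labeled_nc, unmatched_fp1,
#'   featurized).
#' @export
process_day <- function(day_id, run, day_seed) {
  sim <- simulate_day(
    day_id, run$config, run$noise, day_seed,
    n_clusters = run$clusters_per_day, n_singles = run$singles_per_day,
    n_nc = run$nc_per_day, gfp_only_rate = run$gfp_only_rate,
    n_segments = run$segments_per_day
  )
  labeled <- NULL
  segments <- list()
  counts <- c(detected = 0L, gated = 0L, labeled_ctcc = 0L,
              labeled_nc = 0L, unmatched_fp1 = 0L, featurized = 0L)
  for (seg in sim$segments) {
    filt <- bandpass_filter(seg)
    norm <- apply_normalization(filt, sim$calibration)
    sc_peaks <- detect_peaks(norm, "CUMULATIVE", run$sigma_mult)
    fp1_peaks <- detect_peaks(norm, "FP1", run$sigma_mult)
    gated <- width_gate(sc_peaks, run$min_width_points)
    lab <- match_and_label(gated, fp1_peaks, day_id = day_id)
    lab$events$segment_id <- seg$segment_id
    counts["detected"] <- counts["detected"] + nrow(sc_peaks)
    counts["gated"] <- counts["gated"] + nrow(gated)
    counts["labeled_ctcc"] <- counts["labeled_ctcc"] +
      sum(lab$events$label == "CTCC")
    counts["labeled_nc"] <- counts["labeled_nc"] +
      sum(lab$events$label == "NC")
    counts["unmatched_fp1"] <- counts["unmatched_fp1"] +
      nrow(lab$unmatched_fp1)
    labeled <- rbind(labeled, lab$events)
    segments[[paste(day_id, seg$segment_id, sep = "/")]] <- norm
  }
  if (is.null(labeled) || nrow(labeled) == 0) {
    k <- length(intersect(scatter_channels(), run$channels))
    return(list(X = matrix(numeric(0),
                           ncol = (2 * run$half_window + 1) * k),
                y = character(0), day = character(0),
                truth = sim$truth, counts = counts))
  }
  ds <- build_dataset(labeled, segments, method = run$method,
                      channels = run$channels,
                      half_window = run$half_window)
  counts["featurized"] <- nrow(ds$X)
  list(X = ds$X, y = ds$y, day = ds$day, truth = sim$truth,
       counts = counts)
}

#' Run the full synthetic benchmark pipeline
#'
#' Simulates `n_train_days + n_test_days` experiment days, featurizes
#' them, trains a balanced cascade on the training days and evaluates it
#' on the held-out test days. Re-running with an identical configuration
#' reproduces the metrics bit-identically. If `out_dir` is given, writes
#' `labeled_events.csv`, `funnel.csv`, `metrics.json` and `config.json`
#' there.
#'
#' @param run a [pipeline_config()].
#' @param out_dir optional output directory for artifacts.
#' @param verbose print per-stage event counts.
#' @return list with `metrics` (named list), `confusion`, `funnel`
#'   (per-day counts data.frame), `evaluation` (cascade evaluation
#'   object), `cascade`, `train` and `test` dataset summaries.
#' @export
run_pipeline <- function(run = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(run, "bsfc_run_config"))
  n_days <- run$n_train_days + run$n_test_days
  day_ids <- sprintf("day%02d", seq_len(n_days))
  train_days <- day_ids[seq_len(run$n_train_days)]
  test_days <- setdiff(day_ids, train_days)
  X <- NULL; y <- character(0); day <- character(0)
  funnel <- NULL
  for (i in seq_len(n_days)) {
    d <- process_day(day_ids[i], run, derive_seed(run$seed, 100 + i))
    X <- rbind(X, d$X)
    y <- c(y, d$y)
    day <- c(day, d$day)
    funnel <- rbind(funnel, data.frame(day_id = day_ids[i],
                                       t(d$counts)))
    if (verbose) {
      message(sprintf(
        "%s: detected %d -> gated %d -> CTCC %d / NC %d (featurized %d)",
        day_ids[i], d$counts["detected"], d$counts["gated"],
        d$counts["labeled_ctcc"], d$counts["labeled_nc"],
        d$counts["featurized"]))
    }
  }
  tr <- day %in% train_days
  casc <- train_cascade(X[tr, , drop = FALSE], y[tr], run$hp,
                        run$n_models, seed = derive_seed(run$seed, 999))
  ev <- evaluate_cascade(casc, X[!tr, , drop = FALSE])
  cm <- confusion_counts(y[!tr], ev$prediction)
  metrics <- performance_metrics(cm)
  out <- list(metrics = metrics, confusion = cm, funnel = funnel,
              evaluation = ev, cascade = casc,
              train = list(n = sum(tr), days = train_days,
                           n_ctcc = sum(y[tr] == "CTCC"),
                           n_nc = sum(y[tr] == "NC")),
              test = list(n = sum(!tr), days = test_days,
                          n_ctcc = sum(y[!tr] == "CTCC"),
                          n_nc = sum(y[!tr] == "NC"),
                          labels = y[!tr]))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(funnel, file.path(out_dir, "funnel.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(metrics = metrics,
           confusion = cm[c("TP", "FP", "TN", "FN")],
           seed = run$seed),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    cfg <- run
    cfg$noise <- unclass(cfg$noise)
    cfg$hp <- unclass(cfg$hp)
    cfg$config <- unclass(cfg$config)
    jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
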