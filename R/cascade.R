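# The balanced ensemble cascade: 50 Gentle AdaBoost models, each trained
# on all CTCC events plus an equal-size random NC sample, evaluated
# sequentially — only events predicted positive survive to the next
# model. Includes the leave-days-out split enumeration and the evaluation
# harness that averages performance across all training-day combinations.

#' Train a balanced cascade of Gentle AdaBoost models
#'
#' Every model sees the identical CTCC set and an independent
#' equal-size NC resample (without replacement within a model,
#' independent across models). Model order is training order and fully
#' determined by the seed.
#'
#' @param X feature matrix.
#' @param y labels (`"CTCC"`/`"NC"` or -1/+1).
#' @param hp a [boost_hyperparams()].
#' @param n_models number of ensemble members (default 50).
#' @param seed master seed; per-model seeds are derived from it.
#' @return object of class `bsfc_cascade`.
#' @export
train_cascade <- function(X, y, hp = boost_hyperparams(), n_models = 50,
                          seed = 1) {
  yy <- encode_labels(y)
  pos <- which(yy == 1)
  neg <- which(yy == -1)
  if (length(pos) == 0 || length(neg) == 0) {
    stop_bsfc("both classes must be present")
  }
  models <- vector("list", n_models)
  for (k in seq_len(n_models)) {
    nc_idx <- balanced_resample(length(pos), neg,
                                seed = derive_seed(seed, 2 * k))
    idx <- c(pos, nc_idx)
    models[[k]] <- fit_gentleboost(X[idx, , drop = FALSE], yy[idx], hp,
                                   seed = derive_seed(seed, 2 * k + 1))
  }
  structure(
    list(models = models, hp = hp, n_models = n_models, seed = seed,
         n_positive = length(pos)),
    class = "bsfc_cascade"
  )
}

#' @export
print.bsfc_cascade <- function(x, ...) {
  cat(sprintf(
    "<bsfc cascade: %d gentle-boost models, balanced on %d CTCC events>\n",
    x$n_models, x$n_positive))
  invisible(x)
}

#' Evaluate a cascade sequentially
#'
#' Stage 0 survivors are all events; stage k survivors are the stage
#' k - 1 survivors predicted positive by model k. Events predicted
#' negative at any stage stay NC; final CTCC predictions are the
#' survivors of the last stage. Survivor sets are therefore
#' non-increasing in the stage index.
#'
#' @param cascade a `bsfc_cascade` (an empty cascade predicts every event
#'   positive).
#' @param X_test feature matrix.
#' @return list with `prediction` (character `"CTCC"`/`"NC"` per event),
#'   `survivors` (list of integer index vectors per stage, stage 0
#'   first), and `n_survivors` (integer vector).
#' @export
evaluate_cascade <- function(cascade, X_test) {
  n <- nrow(X_test)
  surv <- seq_len(n)
  survivors <- list(surv)
  models <- if (inherits(cascade, "bsfc_cascade")) cascade$models
            else cascade
  for (mod in models) {
    if (length(surv) > 0) {
      cls <- predict(mod, X_test[surv, , drop = FALSE], type = "class")
      surv <- surv[cls == 1]
    }
    survivors[[length(survivors) + 1L]] <- surv
  }
  prediction <- rep("NC", n)
  prediction[surv] <- "CTCC"
  list(prediction = prediction, survivors = survivors,
       n_survivors = lengths(survivors))
}

#' Per-stage predictions of a cascade evaluation
#'
#' The prediction after k stages calls an event CTCC iff it survived
#' stages 1..k; used to trace how performance converges as models are
#' added.
#'
#' @param evaluation result of [evaluate_cascade()].
#' @param n_events number of evaluated events.
#' @param stage stage index (0 = no model applied).
#' @return character vector of predictions after `stage` stages.
#' @export
stage_prediction <- function(evaluation, n_events, stage) {
  pred <- rep("NC", n_events)
  pred[evaluation$survivors[[stage + 1L]]] <- "CTCC"
  pred
}

#' Enumerate leave-days-out training splits
#'
#' All C(n_days, k) ways to pick k training days out of n_days, in
#' deterministic lexicographic order; the remaining days of each plan
#' form its validation set. With the default 10 of 13 days this yields
#' 286 plans.
#'
#' @param n_days total number of training-pool days.
#' @param k days used for training in each plan.
#' @param day_ids optional day identifiers (defaults to
#'   `"day1"..."dayN"`).
#' @return list of plans, each `list(train = ..., validation = ...)`.
#' @export
#' @examples
#' length(enumerate_training_splits(13, 10)) # 286
enumerate_training_splits <- function(n_days = 13, k = 10,
                                      day_ids = NULL) {
  if (k > n_days) stop_bsfc("k = %d exceeds n_days = %d", k, n_days)
  if (is.null(day_ids)) day_ids <- sprintf("day%d", seq_len(n_days))
  if (length(day_ids) != n_days) stop_bsfc("day_ids length mismatch")
  combs <- utils::combn(n_days, k)
  lapply(seq_len(ncol(combs)), function(j) {
    tr <- combs[, j]
    list(train = day_ids[tr], validation = day_ids[-tr])
  })
}

#' Run the multi-split evaluation suite
#'
#' For each split plan: train a cascade on the plan's training days,
#' evaluate it on the fixed held-out test set, and compute the four
#' performance metrics. Aggregates mean and sample standard deviation
#' across plans, and optionally the metric-vs-stage convergence curve of
#' the first plan.
#'
#' @param X,y,day training-pool features, labels and day ids.
#' @param plans list of split plans from [enumerate_training_splits()].
#' @param X_test,y_test held-out test features and labels.
#' @param test_days day ids present in the test set (checked to be
#'   disjoint from every plan's training days).
#' @param hp a [boost_hyperparams()].
#' @param n_models ensemble size per cascade.
#' @param seed master seed.
#' @param track_stages if `TRUE`, also return the per-stage metric curve
#'   of the first plan.
#' @return list with `per_plan` (data.frame of metrics per plan),
#'   `mean`, `sd` (named numeric over the four metrics), and optionally
#'   `stage_curve`.
#' @export
run_evaluation_suite <- function(X, y, day, plans, X_test, y_test,
                                 test_days, hp = boost_hyperparams(),
                                 n_models = 50, seed = 1,
                                 track_stages = FALSE) {
  for (p in plans) {
    if (length(intersect(p$train, test_days)) > 0) {
      stop_bsfc("plan trains on a test day: %s",
                paste(intersect(p$train, test_days), collapse = ", "))
    }
  }
  metric_names <- c("purity", "sensitivity", "specificity", "accuracy")
  per_plan <- matrix(NA_real_, nrow = length(plans), ncol = 4,
                     dimnames = list(NULL, metric_names))
  stage_curve <- NULL
  for (j in seq_along(plans)) {
    rows <- day %in% plans[[j]]$train
    casc <- train_cascade(X[rows, , drop = FALSE], y[rows], hp, n_models,
                          seed = derive_seed(seed, j))
    ev <- evaluate_cascade(casc, X_test)
    cm <- confusion_counts(y_test, ev$prediction)
    per_plan[j, ] <- unlist(performance_metrics(cm))[metric_names]
    if (track_stages && j == 1) {
      stage_curve <- do.call(rbind, lapply(0:n_models, function(s) {
        cs <- confusion_counts(y_test,
                               stage_prediction(ev, nrow(X_test), s))
        data.frame(stage = s, t(unlist(performance_metrics(cs))))
      }))
    }
  }
  per_plan <- as.data.frame(per_plan)
  per_plan$plan <- seq_along(plans)
  agg_mean <- vapply(per_plan[metric_names],
                     function(v) mean(v, na.rm = TRUE), numeric(1))
  agg_sd <- vapply(per_plan[metric_names],
                   function(v) stats::sd(v[!is.na(v)]), numeric(1))
  out <- list(per_plan = per_plan, mean = agg_mean, sd = agg_sd)
  if (track_stages) out$stage_curve <- stage_curve
  out
}
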