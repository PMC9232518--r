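# Gentle AdaBoost with split-limited regression trees as weak learners.
# The boosting loop is implemented here directly: each cycle fits a
# regression tree to the +/-1 labels by weighted least squares, the
# additive score is updated with shrinkage, and observation weights are
# exponentially reweighted. Tree growing itself is delegated to rpart
# (weighted anova fitting), pruned back to the per-tree split cap.

#' Boosting hyperparameters
#'
#' Defaults: 84 learning cycles, at most 102 internal splits per tree,
#' learning rate (shrinkage on each weak learner) 0.899.
#'
#' @param n_learning_cycles number of boosting iterations.
#' @param max_splits_per_tree cap on internal splits per tree.
#' @param learning_rate shrinkage in (0, 1].
#' @return object of class `bsfc_hyperparams`.
#' @export
boost_hyperparams <- function(n_learning_cycles = 84,
                              max_splits_per_tree = 102,
                              learning_rate = 0.899) {
  if (n_learning_cycles < 1 || max_splits_per_tree < 1) {
    stop_bsfc("cycles and splits must be positive")
  }
  if (learning_rate <= 0 || learning_rate > 1) {
    stop_bsfc("learning_rate must be in (0, 1]")
  }
  structure(
    list(n_learning_cycles = as.integer(n_learning_cycles),
         max_splits_per_tree = as.integer(max_splits_per_tree),
         learning_rate = learning_rate),
    class = "bsfc_hyperparams"
  )
}

# grow a weighted regression tree and prune it back to <= max_splits
# internal splits (largest cptable subtree within the cap)
fit_weak_learner <- function(df, w, max_splits) {
  fit <- rpart::rpart(
    .y ~ ., data = df, weights = w, method = "anova",
    control = rpart::rpart.control(cp = 0, minsplit = 2, minbucket = 1,
                                   xval = 0, maxcompete = 0,
                                   maxsurrogate = 0, maxdepth = 30)
  )
  cpt <- fit$cptable
  nsplit <- sum(fit$frame$var != "<leaf>")
  if (!is.null(cpt) && nsplit > max_splits) {
    row <- max(which(cpt[, "nsplit"] <= max_splits))
    fit <- rpart::prune(fit, cp = cpt[row, "CP"])
  }
  fit
}

#' Fit a Gentle AdaBoost model
#'
#' Gentle AdaBoost on labels y in \{-1, +1\}: weights start uniform; each
#' cycle fits a split-limited regression tree f_m to y by weighted least
#' squares, updates the additive score F <- F + nu * f_m, and reweights
#' w_i <- w_i * exp(-y_i * nu * f_m(x_i)) (renormalized). The predicted
#' class is sign(F). Deterministic given the data (the seed only fixes
#' any tie-breaking inside tree growth).
#'
#' @param X numeric matrix or data.frame of features (no missing values).
#' @param y labels: numeric -1/+1, or factor/character with positive
#'   class `"CTCC"`.
#' @param hp a [boost_hyperparams()].
#' @param seed optional integer seed.
#' @return object of class `bsfc_gentleboost`.
#' @export
fit_gentleboost <- function(X, y, hp = boost_hyperparams(), seed = NULL) {
  stopifnot(inherits(hp, "bsfc_hyperparams"))
  y <- encode_labels(y)
  if (length(unique(y)) < 2) {
    stop_bsfc("both classes must be present in y")
  }
  if (!all(is.finite(as.matrix(X)))) stop_bsfc("non-finite feature values")
  if (nrow(X) != length(y)) stop_bsfc("X and y sizes differ")
  df <- as.data.frame(X)
  colnames(df) <- paste0("f", seq_len(ncol(df)))
  df$.y <- y
  n <- nrow(df)
  nu <- hp$learning_rate
  with_seed(seed, {
    w <- rep(1 / n, n)
    Fscore <- numeric(n)
    trees <- vector("list", hp$n_learning_cycles)
    for (m in seq_len(hp$n_learning_cycles)) {
      tree <- fit_weak_learner(df, w, hp$max_splits_per_tree)
      f <- unname(stats::predict(tree, df))
      trees[[m]] <- tree
      Fscore <- Fscore + nu * f
      w <- w * exp(-y * nu * f)
      w <- pmax(w, 1e-300)
      w <- w / sum(w)
    }
    structure(
      list(trees = trees, shrinkage = nu, hp = hp,
           n_features = ncol(X),
           feature_names = setdiff(colnames(df), ".y"),
           train_score = Fscore),
      class = "bsfc_gentleboost"
    )
  })
}

# accepts -1/+1 numerics, or character/factor with CTCC as positive
encode_labels <- function(y) {
  if (is.numeric(y)) {
    if (!all(y %in% c(-1, 1))) stop_bsfc("numeric labels must be -1/+1")
    return(as.numeric(y))
  }
  y <- as.character(y)
  if (!all(y %in% c("CTCC", "NC"))) {
    stop_bsfc("labels must be 'CTCC'/'NC' or -1/+1")
  }
  ifelse(y == "CTCC", 1, -1)
}

#' Predict from a Gentle AdaBoost model
#'
#' @param object a `bsfc_gentleboost` model.
#' @param newdata feature matrix or data.frame.
#' @param type `"score"` for the additive score F(x), `"class"` for
#'   -1/+1 (positive iff F > 0).
#' @param ... unused.
#' @return numeric vector of scores or classes.
#' @export
predict.bsfc_gentleboost <- function(object, newdata,
                                     type = c("score", "class"), ...) {
  type <- match.arg(type)
  if (ncol(newdata) != object$n_features) {
    stop_bsfc("feature dimension %d does not match training dimension %d",
              ncol(newdata), object$n_features)
  }
  df <- as.data.frame(newdata)
  colnames(df) <- object$feature_names
  Fscore <- numeric(nrow(df))
  for (tree in object$trees) {
    Fscore <- Fscore + object$shrinkage * unname(stats::predict(tree, df))
  }
  if (type == "score") Fscore else ifelse(Fscore > 0, 1, -1)
}

#' @export
print.bsfc_gentleboost <- function(x, ...) {
  cat(sprintf(
    "<gentle adaboost: %d trees, <= %d splits each, shrinkage %.3f>\n",
    length(x$trees), x$hp$max_splits_per_tree, x$shrinkage))
  invisible(x)
}

#' Balanced resample of the majority (NC) class
#'
#' Draws `n_positive` distinct NC indices uniformly without replacement
#' from the NC pool, so that each ensemble member trains on exactly equal
#' class counts.
#'
#' @param n_positive number of positive (CTCC) training events.
#' @param nc_pool_indices integer indices of the NC pool.
#' @param seed optional integer seed.
#' @return integer vector of `n_positive` distinct NC indices.
#' @export
balanced_resample <- function(n_positive, nc_pool_indices, seed = NULL) {
  if (length(nc_pool_indices) < n_positive) {
    stop_bsfc("NC pool (%d) smaller than positive count (%d)",
              length(nc_pool_indices), n_positive)
  }
  with_seed(seed, {
    nc_pool_indices[sample.int(length(nc_pool_indices), n_positive)]
  })
}
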