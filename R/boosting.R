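#' Train a gradient-boosted model over selected burden scores
#'
#' Gradient-boosted trees (binomial deviance) with shrinkage fixed at 0.1
#' and a minimum of 10 observations per terminal node. The number of trees
#' and the interaction depth are tuned by repeated stratified
#' cross-validation maximizing the mean held-out AUC over the grid; the
#' final model is refit on the full training data with the winning
#' parameters. Ties in CV AUC go to the smaller depth, then fewer trees.
#' Relative predictor importances are total split-gain attributions
#' normalized to sum to 100.
#'
#' @param X Numeric matrix, subjects x predictors (selected unit scores,
#'   optionally plus the clinical risk score). Only predictors already
#'   chosen by [repeated_cv_select()] should enter; no re-selection happens
#'   here.
#' @param y Binary labels (1/TRUE = case).
#' @param folds CV folds (default 5).
#' @param repeats CV repeats (100 for pathway predictors, 20 for genes).
#' @param grid List with `n_trees` (vector) and `depth` (vector).
#' @param shrinkage Learning rate (default 0.1).
#' @param min_node Minimum observations per terminal node (default 10).
#' @param seed Integer seed.
#' @return An object of class `fitted_model`: the booster, predictor ids,
#'   chosen hyperparameters, the CV AUC grid, normalized importances, and
#'   the seed.
#' @export
train_gbm <- function(X, y, folds = 5L, repeats = 20L,
                      grid = list(n_trees = seq(50L, 500L, by = 50L), depth = 1:3),
                      shrinkage = 0.1, min_node = 10L, seed = 1L) {
  X <- as.matrix(X)
  if (ncol(X) == 0) {
    stop("empty predictor set: no units were selected; fit a clinical-only model instead")
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.integer(as.logical(y))
  if (length(unique(y)) != 2L) stop("y must contain both classes")
  n_trees <- sort(unique(as.integer(grid$n_trees)))
  depths <- sort(unique(as.integer(grid$depth)))
  max_trees <- max(n_trees)

  base_params <- function(depth) list(
    objective = "binary:logistic", eta = shrinkage, max_depth = depth,
    min_child_weight = min_node, subsample = 1, colsample_bytree = 1,
    lambda = 0, alpha = 0, nthread = 1
  )

  auc_sum <- matrix(0, length(depths), length(n_trees),
                    dimnames = list(paste0("depth", depths), paste0("t", n_trees)))
  n_eval <- 0L
  for (r in seq_len(repeats)) {
    fold <- with_seed(seed + 7919L * r, stratified_folds(y, folds))
    for (k in seq_len(folds)) {
      tr <- fold != k
      dtr <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr], nthread = 1)
      for (di in seq_along(depths)) {
        bst <- with_seed(seed + 13L * r + k,
          xgboost::xgb.train(params = base_params(depths[di]), data = dtr,
                             nrounds = max_trees, verbose = 0))
        for (ti in seq_along(n_trees)) {
          pred <- predict(bst, X[!tr, , drop = FALSE],
                          iterationrange = c(1, n_trees[ti]))
          auc_sum[di, ti] <- auc_sum[di, ti] + auc_mw(pred, y[!tr])
        }
      }
      n_eval <- n_eval + 1L
    }
  }
  cv_auc <- auc_sum / n_eval
  best <- which(cv_auc == max(cv_auc), arr.ind = TRUE)[1, ]
  best_depth <- depths[best[1]]
  best_trees <- n_trees[best[2]]

  dall <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  booster <- with_seed(seed,
    xgboost::xgb.train(params = base_params(best_depth), data = dall,
                       nrounds = best_trees, verbose = 0))
  imp_tab <- tryCatch(xgboost::xgb.importance(model = booster), error = function(e) NULL)
  importances <- stats::setNames(rep(0, ncol(X)), colnames(X))
  if (!is.null(imp_tab) && nrow(imp_tab) > 0) {
    importances[imp_tab$Feature] <- imp_tab$Gain
  }
  tot <- sum(importances)
  if (tot > 0) {
    importances <- 100 * importances / tot
  } else {
    warning("model made no splits; all importances are 0")
  }

  structure(list(booster = booster, predictor_ids = colnames(X),
                 n_trees = best_trees, interaction_depth = best_depth,
                 shrinkage = shrinkage, min_node = min_node,
                 cv_auc = cv_auc, importances = importances, seed = seed),
            class = "fitted_model")
}

#' Predict case probabilities from a fitted model
#'
#' @param object A `fitted_model`.
#' @param newdata Matrix or data frame containing the model's predictors.
#' @param ... Unused.
#' @return Numeric vector of predicted probabilities.
#' @export
predict.fitted_model <- function(object, newdata, ...) {
  newdata <- as.matrix(as.data.frame(newdata)[, object$predictor_ids, drop = FALSE])
  predict(object$booster, newdata)
}

#' @exportS3Method base::print
print.fitted_model <- function(x, ...) {
  cat(sprintf("fitted_model: %d predictors, %d trees, depth %d (shrinkage %.2g, min node %d)\n",
              length(x$predictor_ids), x$n_trees, x$interaction_depth,
              x$shrinkage, x$min_node))
  invisible(x)
}

#' Importance-weighted total genetic score
#'
#' Per-subject sum of the model's unit scores, each weighted by its
#' normalized (0-100) relative importance in the fitted model.
#'
#' @param scores Matrix or data frame of unit scores containing every model
#'   predictor as a column.
#' @param model A `fitted_model`.
#' @return Named numeric vector of total scores.
#' @export
total_genetic_score <- function(scores, model) {
  stopifnot(inherits(model, "fitted_model"))
  scores <- as.data.frame(scores)
  miss <- setdiff(model$predictor_ids, names(scores))
  if (length(miss)) stop("missing predictor column(s): ", paste(miss, collapse = ", "))
  M <- as.matrix(scores[model$predictor_ids])
  stats::setNames(as.numeric(M %*% model$importances[model$predictor_ids]),
                  rownames(scores))
}

#' Subjects in the extreme percentiles of a score
#'
#' Retains subjects whose score is at or below the `lower_pct` percentile or
#' at or above the `upper_pct` percentile, with percentiles computed on the
#' evaluated sample by linear interpolation (quantile type 7); boundaries
#' are inclusive.
#'
#' @param scores Named numeric vector of total genetic scores.
#' @param lower_pct,upper_pct Percentile bounds, e.g. 30 and 70 (20/80 or
#'   10/90 in larger replication-style samples).
#' @return Character vector of retained subject names (or integer indices
#'   when unnamed).
#' @export
extreme_percentile_subset <- function(scores, lower_pct = 30, upper_pct = 70) {
  if (lower_pct >= upper_pct) stop("lower_pct must be < upper_pct")
  qs <- stats::quantile(scores, c(lower_pct, upper_pct) / 100, type = 7, names = FALSE)
  keep <- scores <= qs[1] | scores >= qs[2]
  if (sum(keep) < 20) warning("extreme-percentile subset has fewer than 20 subjects; AUC will be unstable")
  if (!is.null(names(scores))) names(scores)[keep] else which(keep)
}
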