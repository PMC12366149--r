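# Type-specific gradient-boosted tree classifiers.
#
# Exact greedy split finding with the gbtree booster and a binary logistic
# objective; hyperparameters chosen by stratified cross-validated AUC over
# a configurable grid; features with zero gain importance are iteratively
# discarded and the search repeated. Training is single-threaded and
# seeded, so retraining reproduces probabilities exactly.

#' Training configuration
#'
#' @param grid Named list of candidate hyperparameter values, expanded to
#'   a full factorial grid. Recognized names: `max_depth`, `eta`,
#'   `nrounds`, `min_child_weight`.
#' @param cv_folds Number of stratified cross-validation folds.
#' @param seed Integer seed controlling fold assignment.
#' @param decision_threshold Probability at or above which a call is
#'   classified positive (inclusive).
#' @param objective,tree_method Passed to the booster; defaults are binary
#'   logistic regression and exact greedy split finding.
#' @return Object of class `training_config`.
#' @export
training_config <- function(grid = list(max_depth = c(3, 5, 7),
                                        eta = c(0.05, 0.1, 0.3),
                                        nrounds = c(100, 300),
                                        min_child_weight = c(1, 5)),
                            cv_folds = 5L, seed = 1L,
                            decision_threshold = 0.5,
                            objective = "binary:logistic",
                            tree_method = "exact") {
  if (!length(grid)) stopf("hyperparameter grid must be non-empty")
  if (decision_threshold <= 0 || decision_threshold >= 1)
    stopf("decision_threshold must lie in (0, 1)")
  structure(list(grid = grid, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed),
                 decision_threshold = decision_threshold,
                 objective = objective, tree_method = tree_method),
            class = "training_config")
}

fm_xy <- function(fm, features = NULL) {
  stopifnot(inherits(fm, "sv_feature_matrix"))
  if (is.null(fm$labels)) stopf("training requires a labeled feature matrix")
  x <- as.matrix(fm$x)
  if (!is.null(features)) {
    missing_cols <- setdiff(features, colnames(x))
    if (length(missing_cols))
      stopf("feature matrix lacks column(s): %s",
            paste(missing_cols, collapse = ", "))
    x <- x[, features, drop = FALSE]
  }
  y <- as.numeric(fm$labels)
  if (length(unique(y)) < 2L)
    stopf("training labels contain a single class")
  list(x = x, y = y)
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

fit_booster <- function(x, y, params, nrounds, config) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  xgboost::xgb.train(
    params = c(list(objective = config$objective,
                    tree_method = config$tree_method,
                    nthread = 1, seed = config$seed), params),
    data = dtrain, nrounds = nrounds, verbose = 0)
}

#' Grid-search training of a type-specific meta-model
#'
#' For every point of the hyperparameter grid, computes mean AUC over
#' stratified k-fold cross-validation (fold assignment fixed by the
#' config seed), selects the best point (ties: first in grid order) and
#' refits on all rows. Deterministic given the seed.
#'
#' @param fm A labeled `sv_feature_matrix` with both classes present.
#' @param config A [training_config()].
#' @param features Optional subset of feature columns to train on
#'   (default: all columns).
#' @return Object of class `meta_model`: booster, ordered `feature_names`,
#'   gain `importances` (0 for unused features), chosen hyperparameters,
#'   cross-validation table, decision threshold, seed, svtype and the
#'   registry hash of the feature configuration.
#' @export
grid_search_train <- function(fm, config = training_config(), features = NULL) {
  stopifnot(inherits(config, "training_config"))
  xy <- fm_xy(fm, features)
  feature_names <- colnames(xy$x)
  fold <- stratified_folds(xy$y, config$cv_folds, config$seed)

  grid <- expand.grid(config$grid, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  aucs <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    g <- as.list(grid[gi, , drop = FALSE])
    nrounds <- g$nrounds %||% 100
    g$nrounds <- NULL
    fold_auc <- vapply(seq_len(config$cv_folds), function(f) {
      tr <- fold != f
      bst <- fit_booster(xy$x[tr, , drop = FALSE], xy$y[tr], g, nrounds, config)
      p <- predict(bst, xgboost::xgb.DMatrix(xy$x[!tr, , drop = FALSE],
                                             nthread = 1))
      yv <- xy$y[!tr]
      if (length(unique(yv)) < 2L) return(NA_real_)
      roc_auc(p, yv == 1)
    }, numeric(1))
    aucs[gi] <- mean(fold_auc, na.rm = TRUE)
  }
  best <- which.max(aucs)  # first index on ties
  bestg <- as.list(grid[best, , drop = FALSE])
  best_nrounds <- bestg$nrounds %||% 100
  bestg$nrounds <- NULL

  booster <- fit_booster(xy$x, xy$y, bestg, best_nrounds, config)
  imp_tab <- xgboost::xgb.importance(model = booster)
  importances <- stats::setNames(numeric(length(feature_names)), feature_names)
  if (!is.null(imp_tab) && nrow(imp_tab))
    importances[imp_tab$Feature] <- imp_tab$Gain

  cv <- data.table::as.data.table(grid)
  cv[, mean_cv_auc := aucs]

  structure(list(
    booster = booster, feature_names = feature_names,
    importances = importances,
    hyperparameters = c(bestg, list(nrounds = best_nrounds)),
    cv = cv[], cv_auc = aucs[best],
    decision_threshold = config$decision_threshold,
    seed = config$seed, svtype = fm$svtype,
    registry_hash = if (!is.null(fm$registry))
      dialect_registry_hash(fm$registry) else NA_character_,
    config = config,
    trained_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    class = "meta_model")
}

#' Iteratively discard zero-importance features and retrain
#'
#' Features whose gain importance is exactly zero contribute nothing to
#' the ensemble; they are dropped and hyperparameter search + training are
#' repeated until no zero-gain feature remains or `max_iter` is reached.
#' Features with positive gain are never removed.
#'
#' @param model A trained `meta_model`.
#' @param fm The labeled feature matrix the model was trained on.
#' @param config The [training_config()] to reuse for retraining.
#' @param max_iter Iteration cap (default 5).
#' @return A `meta_model` whose feature list is a subset of the input's.
#' @export
prune_zero_importance <- function(model, fm, config = model$config,
                                  max_iter = 5L) {
  stopifnot(inherits(model, "meta_model"))
  for (it in seq_len(max_iter)) {
    zero <- names(model$importances)[model$importances == 0]
    if (!length(zero)) break
    keep <- setdiff(model$feature_names, zero)
    if (!length(keep)) stopf("pruning removed every feature")
    model <- grid_search_train(fm, config, features = keep)
  }
  model
}

#' Predict TP probabilities for consensus calls
#'
#' @param model A `meta_model`.
#' @param fm An `sv_feature_matrix` (or plain matrix/data.frame) whose
#'   columns include all of the model's features.
#' @return Numeric vector of probabilities in `[0, 1]`, one per row.
#' @export
predict_probabilities <- function(model, fm) {
  stopifnot(inherits(model, "meta_model"))
  x <- if (inherits(fm, "sv_feature_matrix")) as.matrix(fm$x) else as.matrix(fm)
  missing_cols <- setdiff(model$feature_names, colnames(x))
  if (length(missing_cols))
    stopf("input lacks required feature column(s): %s",
          paste(missing_cols, collapse = ", "))
  x <- x[, model$feature_names, drop = FALSE]
  as.numeric(predict(model$booster, xgboost::xgb.DMatrix(x, nthread = 1)))
}

#' Threshold probabilities into positive/negative calls
#'
#' The bound is inclusive: a probability exactly at the threshold
#' classifies positive.
#'
#' @param probabilities Numeric vector in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5).
#' @return Logical vector.
#' @export
classify <- function(probabilities, threshold = 0.5) {
  if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE))
    stopf("probabilities must lie in [0, 1]")
  probabilities >= threshold
}

#' Save a meta-model artifact
#'
#' Writes the booster in the learner's standard JSON serialization plus a
#' JSON sidecar (feature names, importances, hyperparameters, threshold,
#' registry hash, seed, svtype) into `dir`.
#'
#' @param model A `meta_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_meta_model <- function(model, dir) {
  stopifnot(inherits(model, "meta_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xgboost::xgb.save(model$booster, file.path(dir, "model.json"))
  side <- list(
    feature_names = model$feature_names,
    importances = as.list(model$importances),
    hyperparameters = model$hyperparameters,
    decision_threshold = model$decision_threshold,
    seed = model$seed, svtype = model$svtype,
    registry_hash = model$registry_hash,
    cv_auc = model$cv_auc, trained_at = model$trained_at)
  jsonlite::write_json(side, file.path(dir, "model_meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load a meta-model artifact saved by [save_meta_model()]
#'
#' @param dir Artifact directory.
#' @return A `meta_model`.
#' @export
load_meta_model <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "model_meta.json"),
                              simplifyVector = TRUE)
  booster <- xgboost::xgb.load(file.path(dir, "model.json"))
  structure(list(
    booster = booster, feature_names = side$feature_names,
    importances = unlist(side$importances),
    hyperparameters = side$hyperparameters,
    cv = NULL, cv_auc = side$cv_auc,
    decision_threshold = side$decision_threshold,
    seed = side$seed, svtype = side$svtype,
    registry_hash = side$registry_hash,
    config = NULL, trained_at = side$trained_at),
    class = "meta_model")
}

#' @export
print.meta_model <- function(x, ...) {
  cat(sprintf("meta_model (%s): %d features, cv AUC %.3f, threshold %.2f\n",
              x$svtype %||% "?", length(x$feature_names),
              x$cv_auc %||% NA, x$decision_threshold))
  top <- head(sort(x$importances, decreasing = TRUE), 5)
  cat("top gain:", paste(sprintf("%s=%.3f", names(top), top), collapse = ", "),
      "\n")
  invisible(x)
}
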