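# Gradient-boosted classifiers on atlas coordinates. Trees are grown
# leaf-wise (lossguide) with L1/L2 penalties and balanced class weights,
# tuned by stratified k-fold cross-validation.

#' @keywords internal
#' @noRd
.default_boost_grid <- function() {
  expand.grid(eta = c(0.05, 0.1), max_leaves = c(7, 15, 31),
              alpha = c(0, 0.1, 1), lambda = c(0, 0.1, 1),
              KEEP.OUT.ATTRS = FALSE)
}

#' @keywords internal
#' @noRd
.boost_params <- function(row, objective, num_class = NULL) {
  p <- list(objective = objective, eta = row$eta, max_leaves = row$max_leaves,
            max_depth = 0, grow_policy = "lossguide", alpha = row$alpha,
            lambda = row$lambda, nthread = 1)
  if (!is.null(num_class)) p$num_class <- num_class
  p
}

# One cross-validation pass at fixed parameters: out-of-fold probabilities
# plus the mean early-stopped iteration count.
#' @keywords internal
#' @noRd
.boost_cv_pass <- function(x, y_int, weights, folds, params, nrounds) {
  n_folds <- max(folds)
  num_class <- params$num_class %||% 1
  oof <- matrix(NA_real_, length(y_int), num_class)
  iters <- integer(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    dtr <- xgboost::xgb.DMatrix(x[tr, , drop = FALSE], label = y_int[tr],
                                weight = weights[tr])
    dte <- xgboost::xgb.DMatrix(x[!tr, , drop = FALSE], label = y_int[!tr],
                                weight = weights[!tr])
    bst <- xgboost::xgb.train(params = params, data = dtr, nrounds = nrounds,
                              evals = list(val = dte),
                              early_stopping_rounds = 20, verbose = 0)
    it <- xgboost::xgb.attr(bst, "best_iteration")
    iters[f] <- if (is.null(it) || !nzchar(it)) nrounds else as.integer(it) + 1L
    pr <- predict(bst, xgboost::xgb.DMatrix(x[!tr, , drop = FALSE]))
    oof[!tr, ] <- as.matrix(pr)
  }
  list(oof = oof, nrounds = max(10L, as.integer(round(mean(iters)))))
}

# Grid tuning by inner cross-validation, then a fresh outer CV pass at the
# winning configuration: the reported out-of-fold metrics come from the outer
# pass, so they are not inflated by picking the best of many grid points.
#' @keywords internal
#' @noRd
.boost_tune <- function(x, y_int, weights, folds, objective, num_class,
                        grid, nrounds, metric_fn, eval_metric) {
  best <- list(score = -Inf)
  for (g in seq_len(nrow(grid))) {
    params <- .boost_params(grid[g, ], objective, num_class)
    params$eval_metric <- eval_metric
    cvp <- .boost_cv_pass(x, y_int, weights, folds, params, nrounds)
    score <- metric_fn(cvp$oof)
    if (score > best$score) {
      best <- list(score = score, row = grid[g, ], nrounds = cvp$nrounds,
                   params = params)
    }
  }
  outer_folds <- .stratified_folds(y_int, max(folds))
  outer <- .boost_cv_pass(x, y_int, weights, outer_folds, best$params,
                          nrounds)
  best$oof <- outer$oof
  best$score <- metric_fn(outer$oof)
  best
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train the multi-class subtype classifier on atlas coordinates
#'
#' Fits a gradient-boosted decision-tree ensemble over the 5-D embedding
#' coordinates to predict disease subtype. Hyperparameters (learning rate,
#' leaf count, L1/L2 penalties) are chosen from a small grid by macro-F1 in
#' stratified `n_folds`-fold cross-validation with class weights inversely
#' proportional to class frequency. Classes with fewer members than `n_folds`
#' are merged into an `"other"` stratum with a warning.
#'
#' @param coords Samples x dims coordinate matrix (from [fit_embedding()]).
#' @param labels Subtype label per sample (factor or character; >= 2 classes).
#' @param n_folds Cross-validation folds.
#' @param seed Integer seed (fold assignment).
#' @param grid Hyperparameter grid (data.frame with `eta`, `max_leaves`,
#'   `alpha`, `lambda`); defaults to the package grid.
#' @param nrounds Maximum boosting rounds (early stopping on the held-out
#'   fold).
#' @return Object of class `subtype_model`: the fitted booster, ordered class
#'   list, chosen hyperparameters, per-class CV concordance (held-out recall),
#'   and the pooled out-of-fold metrics.
#' @export
train_subtype <- function(coords, labels, n_folds = 5, seed = 42,
                          grid = .default_boost_grid(), nrounds = 200) {
  coords <- as.matrix(coords)
  labels <- as.character(labels)
  .assert(length(labels) == nrow(coords), "labels must align with coords rows")
  tab <- table(labels)
  .assert(length(tab) >= 2, "need at least 2 classes")
  small <- names(tab)[tab < n_folds]
  if (length(small) > 0) {
    warning(sprintf("classes merged into 'other' (fewer than %d members): %s",
                    n_folds, paste(small, collapse = ", ")))
    labels[labels %in% small] <- "other"
    tab <- table(labels)
    .assert(length(tab) >= 2, "merging left a single class")
  }
  classes <- names(tab)
  y_int <- match(labels, classes) - 1L
  w <- as.vector(length(labels) / (length(classes) * tab[labels]))

  set.seed(seed)
  folds <- .stratified_folds(labels, n_folds)
  macro_f1_of <- function(oof) {
    pred <- classes[max.col(oof, ties.method = "first")]
    classification_metrics(labels, pred, classes = classes)$macro_f1
  }
  best <- .boost_tune(coords, y_int, w, folds, "multi:softprob",
                      length(classes), grid, nrounds, macro_f1_of, "mlogloss")

  params <- .boost_params(best$row, "multi:softprob", length(classes))
  dall <- xgboost::xgb.DMatrix(coords, label = y_int, weight = w)
  set.seed(seed)
  booster <- xgboost::xgb.train(params = params, data = dall,
                                nrounds = best$nrounds, verbose = 0)

  n_features <- ncol(coords)
  oof_pred <- classes[max.col(best$oof, ties.method = "first")]
  per_class <- vapply(classes, function(cl) {
    mean(oof_pred[labels == cl] == cl)
  }, numeric(1))
  cv_metrics <- classification_metrics(labels, oof_pred, probs = best$oof,
                                       classes = classes)
  structure(list(booster = booster, classes = classes, n_features = n_features,
                 best_params = best$row, nrounds = best$nrounds,
                 per_class_concordance = per_class, cv_metrics = cv_metrics,
                 n_folds = n_folds, seed = seed),
            class = "subtype_model")
}

#' Predict subtype probabilities, top label, and confidence
#'
#' @param model A [train_subtype()] result.
#' @param coords Samples x dims coordinate matrix (same width as training).
#' @return list with `probs` (samples x classes, rows sum to 1), `label`
#'   (argmax class; ties broken by class-list order), and `confidence`
#'   (maximum probability).
#' @export
predict_subtype <- function(model, coords) {
  .assert(inherits(model, "subtype_model"), "model must be a subtype_model")
  coords <- as.matrix(coords)
  .assert(ncol(coords) == model$n_features, "coords must have %d columns, got %d",
          model$n_features, ncol(coords))
  probs <- as.matrix(predict(model$booster, xgboost::xgb.DMatrix(coords)))
  probs <- probs / rowSums(probs)   # remove float32 rounding from the booster
  colnames(probs) <- model$classes
  rownames(probs) <- rownames(coords)
  top <- max.col(probs, ties.method = "first")
  list(probs = probs, label = model$classes[top],
       confidence = probs[cbind(seq_len(nrow(probs)), top)])
}

#' Train the binary five-year-mortality classifier
#'
#' Trains a gradient-boosted classifier of death within `horizon` months on
#' atlas coordinates. Only samples with a determinate five-year status enter
#' training: an event before the horizon labels "dead", follow-up reaching the
#' horizon without an event labels "alive"; samples censored before the
#' horizon are excluded and their count recorded. Tuning mirrors
#' [train_subtype()] with out-of-fold AUC as the selection metric.
#'
#' @param coords Samples x dims coordinate matrix.
#' @param os_time,os_event Overall-survival time (months) and event indicator.
#' @param n_folds,seed,grid,nrounds As in [train_subtype()].
#' @param horizon Horizon in months defining the binary target.
#' @return Object of class `risk_model` with the booster, chosen
#'   hyperparameters, out-of-fold CV AUC, and `n_excluded` (censored before
#'   the horizon).
#' @export
train_risk <- function(coords, os_time, os_event, n_folds = 5, seed = 42,
                       grid = .default_boost_grid(), nrounds = 200,
                       horizon = 60) {
  coords <- as.matrix(coords)
  .assert(length(os_time) == nrow(coords) && length(os_event) == nrow(coords),
          "survival vectors must align with coords rows")
  status <- .status_at_horizon(os_time, os_event, horizon)
  keep <- !is.na(status)
  n_excluded <- sum(!keep)
  x <- coords[keep, , drop = FALSE]
  y <- as.integer(status[keep])
  .assert(sum(y) >= 10, "need at least 10 death events before the horizon (got %d)",
          sum(y))
  .assert(sum(y == 0) >= n_folds, "too few survivors for %d-fold CV", n_folds)
  tab <- table(y)
  w <- as.vector(length(y) / (2 * tab[as.character(y)]))

  set.seed(seed)
  folds <- .stratified_folds(y, n_folds)
  auc_of <- function(oof) .rank_auc(oof[, 1], y == 1)
  best <- .boost_tune(x, y, w, folds, "binary:logistic", NULL, grid, nrounds,
                      auc_of, "logloss")

  params <- .boost_params(best$row, "binary:logistic")
  dall <- xgboost::xgb.DMatrix(x, label = y, weight = w)
  set.seed(seed)
  booster <- xgboost::xgb.train(params = params, data = dall,
                                nrounds = best$nrounds, verbose = 0)
  structure(list(booster = booster, best_params = best$row,
                 n_features = ncol(coords),
                 nrounds = best$nrounds, cv_auc = best$score,
                 n_excluded = n_excluded, horizon = horizon, seed = seed),
            class = "risk_model")
}

#' Predict the probability of death within the model horizon
#'
#' @param model A [train_risk()] result.
#' @param coords Samples x dims coordinate matrix.
#' @return Numeric vector of death probabilities in \[0, 1\].
#' @export
predict_risk <- function(model, coords) {
  .assert(inherits(model, "risk_model"), "model must be a risk_model")
  coords <- as.matrix(coords)
  .assert(ncol(coords) == model$n_features, "coords must have %d columns, got %d",
          model$n_features, ncol(coords))
  as.vector(predict(model$booster, xgboost::xgb.DMatrix(coords)))
}

#' Classification performance metrics
#'
#' Computes accuracy, macro and frequency-weighted F1, Cohen's kappa,
#' confusion counts, and (when probabilities are supplied) one-vs-rest
#' per-class AUC — the metric set used to benchmark the subtype classifier.
#'
#' @param y_true,y_pred Aligned label vectors. Every predicted label must
#'   belong to `classes`.
#' @param probs Optional samples x classes probability matrix for per-class
#'   AUC.
#' @param classes Ordered class list; defaults to the classes present in
#'   `y_true`.
#' @return list with `accuracy`, `macro_f1`, `weighted_f1`, `kappa`,
#'   `per_class_auc` (or `NULL`), `per_class_f1`, and the `confusion` matrix
#'   (true x predicted).
#' @export
classification_metrics <- function(y_true, y_pred, probs = NULL,
                                   classes = NULL) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  .assert(length(y_true) == length(y_pred), "y_true and y_pred must align")
  if (is.null(classes)) classes <- sort(unique(y_true))
  bad <- setdiff(y_pred, classes)
  .assert(length(bad) == 0, "predicted class not in class list: %s",
          paste(bad, collapse = ", "))
  .assert(all(y_true %in% classes), "true class not in class list")

  cm <- table(factor(y_true, classes), factor(y_pred, classes))
  n <- length(y_true)
  acc <- sum(diag(cm)) / n

  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  support <- rowSums(cm)
  macro_f1 <- mean(f1[support > 0])
  weighted_f1 <- sum(f1 * support) / n

  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (pe < 1) (acc - pe) / (1 - pe) else 0

  per_class_auc <- NULL
  if (!is.null(probs)) {
    probs <- as.matrix(probs)
    .assert(ncol(probs) == length(classes),
            "probs must have one column per class")
    per_class_auc <- vapply(seq_along(classes), function(k) {
      pos <- y_true == classes[k]
      if (!any(pos) || all(pos)) return(NA_real_)
      .rank_auc(probs[, k], pos)
    }, numeric(1))
    names(per_class_auc) <- classes
  }
  list(accuracy = acc, macro_f1 = macro_f1, weighted_f1 = weighted_f1,
       kappa = kappa, per_class_auc = per_class_auc,
       per_class_f1 = stats::setNames(f1, classes), confusion = cm)
}
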