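#' Machine-learning configuration
#'
#' Defaults mirror the study's classification stage: 6-fold stratified
#' cross-validation, 10,000 stability repeats (scale down for quick runs),
#' early stopping after 10 rounds without log-loss improvement on a held-out
#' 20% slice of each training fold, and an AUC plateau tolerance used by the
#' iterative feature addition.
#'
#' @param k_folds,n_stability_repeats,early_stopping_rounds,plateau_epsilon,seed
#'   See description.
#' @param eval_metric Early-stopping metric (`"logloss"`).
#' @param backend `"xgboost"` (boosted trees) or `"tree"` (the package's
#'   decision tree, mainly for tests).
#' @return A list of class `ml_config`.
#' @export
ml_config <- function(k_folds = 6, n_stability_repeats = 10000,
                      early_stopping_rounds = 10, eval_metric = "logloss",
                      plateau_epsilon = 0.01,
                      backend = c("xgboost", "tree"), seed = 0L) {
  backend <- match.arg(backend)
  stopifnot(k_folds >= 2, n_stability_repeats >= 1)
  structure(list(k_folds = k_folds,
                 n_stability_repeats = n_stability_repeats,
                 early_stopping_rounds = early_stopping_rounds,
                 eval_metric = eval_metric,
                 plateau_epsilon = plateau_epsilon,
                 backend = backend, seed = as.integer(seed)),
            class = "ml_config")
}

#' Build a samples x features table from a Z-scored matrix
#'
#' Selects proteins as feature columns. Intensities are expected to be
#' Z-scored within cohorts beforehand ([zscore_proteins()]). Missing values
#' are replaced with 0 when `impute_zero` is `TRUE`; backends that handle
#' missingness natively (XGBoost) take the table with `NA` kept.
#'
#' @param zmatrix Output of [zscore_proteins()].
#' @param proteins Character vector of protein ids to use as features.
#' @param impute_zero Replace missing values with 0.
#' @return A numeric matrix (samples x features, rownames = sample ids).
#' @export
prepare_feature_table <- function(zmatrix, proteins, impute_zero = TRUE) {
  if (!length(proteins)) stop("empty protein subset", call. = FALSE)
  missing <- setdiff(proteins, zmatrix$protein_id)
  if (length(missing)) {
    stop("unknown protein(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  vals <- intensity_values(zmatrix)
  ft <- t(vals[match(proteins, zmatrix$protein_id), , drop = FALSE])
  colnames(ft) <- proteins
  if (impute_zero) ft[is.na(ft)] <- 0
  ft
}

#' Minimum tree depth reaching full training accuracy
#'
#' Fits trees of increasing depth until the training accuracy reaches 1.0
#' and reports the depth, the features the final tree uses (root first,
#' then by level and impurity decrease) and the accuracy trajectory.
#'
#' @param x,y As in [fit_decision_tree()].
#' @param depth_max_cap Largest depth tried before giving up.
#' @return A list: `depth`, `features`, `accuracy_by_depth` tibble, `tree`.
#' @export
min_depth_for_full_training_accuracy <- function(x, y, depth_max_cap = 12) {
  y01 <- as.integer(as.logical(y))
  acc <- numeric(0)
  for (depth in seq_len(depth_max_cap)) {
    tree <- fit_decision_tree(x, y01, max_depth = depth)
    a <- mean(predict(tree, x, type = "class") == y01)
    acc[depth] <- a
    if (a == 1) {
      return(list(depth = depth, features = tree_feature_order(tree),
                  accuracy_by_depth = tibble::tibble(
                    depth = seq_len(depth), accuracy = acc),
                  tree = tree))
    }
  }
  stop("training accuracy 1.0 not reached by depth ", depth_max_cap,
       "; best accuracy ", signif(max(acc), 4),
       " (conflicting duplicate feature vectors?)", call. = FALSE)
}

#' Feature-rank stability under resampling
#'
#' Repeatedly refits the decision tree with the sample order shuffled and
#' split ties broken at random, recording which feature sits at the root
#' (rank 1) and which features occupy the second-level nodes (ranks 2-3).
#'
#' @param x,y As in [fit_decision_tree()].
#' @param n_repeats Number of refits.
#' @param seed Integer seed.
#' @param max_depth Tree depth used for each refit.
#' @return A tibble per feature: `feature`, `rank1_freq`, `rank23_freq`.
#' @export
feature_rank_stability <- function(x, y, n_repeats = 1000, seed = 0L,
                                   max_depth = 6) {
  x <- as.matrix(x)
  y01 <- as.integer(as.logical(y))
  feats <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  colnames(x) <- feats
  rank1 <- setNames(numeric(length(feats)), feats)
  rank23 <- setNames(numeric(length(feats)), feats)
  withr::with_seed(seed, {
    for (b in seq_len(n_repeats)) {
      ord <- sample.int(nrow(x))
      tree <- fit_decision_tree(x[ord, , drop = FALSE], y01[ord],
                                max_depth = max_depth, tie_break = "random")
      nd <- tree$nodes
      root_f <- nd$feature[1]
      if (!is.na(root_f)) rank1[feats[root_f]] <- rank1[feats[root_f]] + 1
      lvl2 <- unique(nd$feature[nd$depth == 2 & !is.na(nd$feature)])
      for (f in lvl2) rank23[feats[f]] <- rank23[feats[f]] + 1
    }
  })
  tibble::tibble(feature = feats, rank1_freq = unname(rank1) / n_repeats,
                 rank23_freq = unname(rank23) / n_repeats)
}

# Stratified fold assignment: within each class, shuffled samples are dealt
# round-robin so fold class proportions match the data and every sample
# lands in exactly one fold.
stratified_folds <- function(y, k) {
  y <- as.integer(as.logical(y))
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Fit the configured backend on (x, y) and return a score function.
fit_backend <- function(x, y, config) {
  if (config$backend == "tree") {
    xt <- x; xt[is.na(xt)] <- 0
    tree <- fit_decision_tree(xt, y, max_depth = 6)
    return(function(newx) {
      newx[is.na(newx)] <- 0
      predict(tree, newx, type = "prob")
    })
  }
  # xgboost with early stopping on a held-out 20% slice of the training fold
  val_idx <- stratified_folds(y, 5) == 1
  dtrain <- xgboost::xgb.DMatrix(x[!val_idx, , drop = FALSE],
                                 label = y[!val_idx], nthread = 1)
  dval <- xgboost::xgb.DMatrix(x[val_idx, , drop = FALSE],
                               label = y[val_idx], nthread = 1)
  fit <- xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  eval_metric = config$eval_metric, nthread = 1),
    data = dtrain, nrounds = 200,
    evals = list(val = dval),
    early_stopping_rounds = config$early_stopping_rounds,
    verbose = 0
  )
  function(newx) {
    predict(fit, xgboost::xgb.DMatrix(newx, nthread = 1))
  }
}

#' ROC curve and AUC
#'
#' The AUC equals the probability that a random positive outscores a random
#' negative, with 0.5 credit for ties (Mann-Whitney identity, computed via
#' ranks). The curve is the usual step function over score thresholds.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels (logical or 0/1); both classes required.
#' @return A list with `auc` and `curve` (tibble `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required", call. = FALSE)
  r <- rank(scores)  # average ranks give the tie-corrected U statistic
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(y[ord] == 1)
  fp <- cumsum(y[ord] == 0)
  keep <- c(diff(scores[ord]) != 0, TRUE)  # one point per distinct score
  curve <- tibble::tibble(fpr = c(0, fp[keep] / n0),
                          tpr = c(0, tp[keep] / n1))
  list(auc = auc, curve = curve)
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' @param tp,fn,tn,fp Confusion-matrix counts; each class must be
#'   represented (`tp + fn >= 1`, `tn + fp >= 1`).
#' @return A tibble with `sensitivity`, `specificity`, `accuracy`.
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  if (any(c(tp, fn, tn, fp) < 0) || tp + fn < 1 || tn + fp < 1) {
    stop("invalid confusion counts", call. = FALSE)
  }
  tibble::tibble(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / (tp + fn + tn + fp)
  )
}

#' Iterative feature addition with AUC plateau
#'
#' Adds features one at a time in the given importance order, computing the
#' cross-validated mean AUC for each prefix, and selects the smallest
#' feature count whose mean AUC is within `plateau_epsilon` of the maximum.
#'
#' @param x Samples x features matrix (superset of `features`).
#' @param y Binary labels.
#' @param features Ordered character vector of feature names.
#' @param config An [ml_config()].
#' @return A list: `auc_by_count` tibble (`n_features`, `mean_auc`) and
#'   `selected_count`.
#' @export
iterative_feature_addition <- function(x, y, features, config = ml_config()) {
  if (!length(features)) stop("ordered feature list is empty", call. = FALSE)
  aucs <- vapply(seq_along(features), function(m) {
    rep <- kfold_evaluate(x, y, features[seq_len(m)], config)
    rep$mean_auc
  }, 0)
  sel <- which(aucs >= max(aucs) - config$plateau_epsilon)[1]
  list(auc_by_count = tibble::tibble(n_features = seq_along(features),
                                     mean_auc = aucs),
       selected_count = sel)
}

#' Stratified k-fold ensemble evaluation
#'
#' Shuffles and splits the samples into stratified folds (every sample is
#' in the test set exactly once), fits the boosted-tree backend on each
#' training fold (early stopping on a held-out slice), scores the test
#' fold, and reports per-fold ROC/AUC plus the combined confusion matrix
#' over all pooled test folds at a probability cutoff of 0.5 ("net
#' reclassification").
#'
#' @inheritParams iterative_feature_addition
#' @param features Feature names to use (default all columns of `x`).
#' @return An object of class `ml_report`: `folds` (tibble `fold`, `auc`,
#'   `n_test`), `roc` (tibble `fold`, `fpr`, `tpr`), `mean_auc`,
#'   `confusion` (tp/fn/tn/fp), `metrics` ([confusion_metrics()] row) and
#'   `predictions`.
#' @export
kfold_evaluate <- function(x, y, features = colnames(x),
                           config = ml_config()) {
  x <- as.matrix(x)[, features, drop = FALSE]
  y01 <- as.integer(as.logical(y))
  k <- config$k_folds
  withr::with_seed(config$seed, {
    fold <- stratified_folds(y01, k)
    if (any(tapply(y01, fold, function(v) length(unique(v))) < 2)) {
      stop("a fold lost a class; use more samples or another seed",
           call. = FALSE)
    }
    scores <- numeric(length(y01))
    fold_rows <- list(); roc_rows <- list()
    for (f in seq_len(k)) {
      test <- fold == f
      score_fun <- fit_backend(x[!test, , drop = FALSE], y01[!test], config)
      s <- score_fun(x[test, , drop = FALSE])
      scores[test] <- s
      rc <- roc_auc(s, y01[test])
      fold_rows[[f]] <- tibble::tibble(fold = f, auc = rc$auc,
                                       n_test = sum(test))
      roc_rows[[f]] <- dplyr::mutate(rc$curve, fold = f)
    }
  })
  folds <- dplyr::bind_rows(fold_rows)
  pred_class <- as.integer(scores >= 0.5)
  tp <- sum(pred_class == 1 & y01 == 1)
  fn <- sum(pred_class == 0 & y01 == 1)
  tn <- sum(pred_class == 0 & y01 == 0)
  fp <- sum(pred_class == 1 & y01 == 0)
  structure(list(
    folds = folds,
    roc = dplyr::bind_rows(roc_rows),
    mean_auc = mean(folds$auc),
    confusion = c(tp = tp, fn = fn, tn = tn, fp = fp),
    metrics = confusion_metrics(tp, fn, tn, fp),
    predictions = tibble::tibble(sample = seq_along(y01), fold = fold,
                                 score = scores, label = y01)
  ), class = "ml_report")
}

#' @export
print.ml_report <- function(x, ...) {
  cat("# k-fold evaluation:", nrow(x$folds), "folds, mean AUC",
      round(x$mean_auc, 3), "\n")
  cat("  confusion tp/fn/tn/fp:", paste(x$confusion, collapse = "/"),
      "| sens", round(x$metrics$sensitivity, 3),
      "spec", round(x$metrics$specificity, 3),
      "acc", round(x$metrics$accuracy, 3), "\n")
  invisible(x)
}

#' Broom-style tidiers for k-fold evaluation reports
#'
#' `tidy()` returns the per-fold AUC table; `glance()` a one-row summary
#' with mean AUC and the combined confusion metrics.
#'
#' @param x An `ml_report`.
#' @param ... Unused.
#' @export
tidy.ml_report <- function(x, ...) x$folds

#' @rdname tidy.ml_report
#' @export
glance.ml_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(mean_auc = x$mean_auc,
                   tp = x$confusion[["tp"]], fn = x$confusion[["fn"]],
                   tn = x$confusion[["tn"]], fp = x$confusion[["fp"]]),
    x$metrics
  )
}
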