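#' Rank-based (Mann-Whitney) AUC
#'
#' @param scores numeric scores, higher = more positive.
#' @param positive logical vector, `TRUE` for positive instances.
#' @return AUC in \[0, 1\], or `NA` if either class is empty. Ties receive
#'   mid-ranks, so exchangeable scores give 0.5.
#' @keywords internal
auc_rank <- function(scores, positive) {
  npos <- sum(positive)
  nneg <- sum(!positive)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' One-vs-rest classification metrics
#'
#' For every class `c` present in the truth, builds the one-vs-rest confusion
#' table (positive = `c`) and computes per-class Accuracy = (TP+TN)/n,
#' Specificity = TN/(TN+FP), Sensitivity = TP/(TP+FN), and rank-based ROC-AUC
#' from the class's score column. Macro averages over classes are reported,
#' together with the plain multiclass fraction-correct (`accuracy`), which is
#' the headline accuracy used throughout the package. Classes that appear in
#' predictions or scores but never in the truth have undefined sensitivity
#' and are excluded from the macro averages with a warning.
#'
#' @param true_labels integer/factor truth.
#' @param predicted_labels integer/factor predictions, same length.
#' @param class_scores optional matrix of per-class scores (colnames = class
#'   codes); required for AUC.
#' @return list with `accuracy` (fraction correct), `macro_ovr_accuracy`,
#'   `specificity`, `sensitivity`, `auc` (macro averages) and `per_class`
#'   data frame holding the TP/TN/FP/FN counts and per-class metrics.
#' @export
ovr_metrics <- function(true_labels, predicted_labels, class_scores = NULL) {
  true_labels <- as.integer(as.character(true_labels))
  predicted_labels <- as.integer(as.character(predicted_labels))
  if (length(true_labels) != length(predicted_labels)) {
    abort_ramanglu("label vectors must have equal length",
                   class = "ramanglu_invalid_params")
  }
  n <- length(true_labels)
  present <- sort(unique(true_labels))
  extra <- setdiff(unique(predicted_labels), present)
  if (!is.null(class_scores)) {
    extra <- union(extra, setdiff(as.integer(colnames(class_scores)), present))
  }
  if (length(extra)) {
    warning(sprintf("class(es) %s absent from the truth: sensitivity undefined, excluded from macro averages",
                    paste(sort(extra), collapse = ", ")))
  }
  rows <- lapply(present, function(cl) {
    tp <- sum(true_labels == cl & predicted_labels == cl)
    fn <- sum(true_labels == cl & predicted_labels != cl)
    fp <- sum(true_labels != cl & predicted_labels == cl)
    tn <- n - tp - fn - fp
    auc <- NA_real_
    if (!is.null(class_scores) && as.character(cl) %in% colnames(class_scores)) {
      auc <- auc_rank(class_scores[, as.character(cl)], true_labels == cl)
    }
    data.frame(class = cl, TP = tp, TN = tn, FP = fp, FN = fn,
               accuracy = (tp + tn) / n,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               sensitivity = tp / (tp + fn),
               auc = auc)
  })
  per_class <- do.call(rbind, rows)
  list(accuracy = mean(true_labels == predicted_labels),
       macro_ovr_accuracy = mean(per_class$accuracy),
       specificity = mean(per_class$specificity, na.rm = TRUE),
       sensitivity = mean(per_class$sensitivity),
       auc = if (all(is.na(per_class$auc))) NA_real_ else mean(per_class$auc, na.rm = TRUE),
       per_class = per_class)
}

#' Cross-validation configuration
#'
#' Repeated stratified k-fold: each repeat draws a fresh stratified partition
#' into `k` folds, each fold serves once as the test set, giving
#' `k * n_repeats` train/test iterations. The defaults (k = 5, 90 repeats)
#' give 450 iterations; with 10 classes of 5 replicates each test fold then
#' holds exactly one sample of every class.
#'
#' @param k number of folds (>= 2).
#' @param n_repeats number of independent partitions.
#' @param seed master seed; repeat partitions and model fits derive from it.
#' @param stratified preserve class counts per fold (default `TRUE`).
#' @return an object of class `cv_config`.
#' @export
cv_config <- function(k = 5, n_repeats = 90, seed = 1L, stratified = TRUE) {
  stopifnot_scalar_count(k, "k", min = 2)
  stopifnot_scalar_count(n_repeats, "n_repeats", min = 1)
  structure(list(k = as.integer(k), n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed), stratified = isTRUE(stratified)),
            class = "cv_config")
}

stratified_folds <- function(y, k, stratified, seed) {
  withr::with_seed(seed, {
    fold <- integer(length(y))
    if (stratified) {
      for (cl in unique(y)) {
        idx <- which(y == cl)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      idx <- sample.int(length(y))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Evaluate a classifier by repeated stratified cross-validation
#'
#' @param features samples-by-features numeric matrix.
#' @param labels integer class labels, one per row.
#' @param model a [model_spec()].
#' @param cv a [cv_config()].
#' @return object of class `eval_report`: `per_iteration` data frame (one row
#'   per train/test iteration with accuracy, macro OvR accuracy, specificity,
#'   sensitivity, AUC), `means` over all iterations, `n_iterations`, `model`.
#' @export
evaluate_repeated_cv <- function(features, labels, model, cv = cv_config()) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (nrow(features) != length(labels)) {
    abort_ramanglu("`features` rows and `labels` length differ",
                   class = "ramanglu_invalid_params")
  }
  counts <- table(labels)
  if (cv$stratified && any(counts < cv$k)) {
    abort_ramanglu(
      sprintf("stratified %d-fold CV needs >= %d samples per class; class(es) %s too small",
              cv$k, cv$k, paste(names(counts)[counts < cv$k], collapse = ", ")),
      class = "ramanglu_stratification_error")
  }
  rows <- vector("list", cv$n_repeats * cv$k)
  it <- 0L
  for (rep_i in seq_len(cv$n_repeats)) {
    fold <- stratified_folds(labels, cv$k, cv$stratified,
                             derive_seed(cv$seed, rep_i))
    for (f in seq_len(cv$k)) {
      it <- it + 1L
      test <- fold == f
      fit <- fit_classifier(model, features[!test, , drop = FALSE],
                            labels[!test],
                            seed = derive_seed(model$seed, it))
      pred <- predict_classifier(fit, features[test, , drop = FALSE])
      m <- ovr_metrics(labels[test], pred$labels, pred$scores)
      rows[[it]] <- data.frame(
        repeat_id = rep_i, fold = f, n_test = sum(test),
        accuracy = m$accuracy, macro_ovr_accuracy = m$macro_ovr_accuracy,
        specificity = m$specificity, sensitivity = m$sensitivity, auc = m$auc)
    }
  }
  per_iteration <- do.call(rbind, rows)
  means <- colMeans(per_iteration[, c("accuracy", "macro_ovr_accuracy",
                                      "specificity", "sensitivity", "auc")],
                    na.rm = TRUE)
  structure(list(model = model$name, hyperparams = model$hyperparams,
                 n_iterations = it, per_iteration = per_iteration,
                 means = as.list(means), cv = cv),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s: %d iterations | Acc %.2f%% Sp %.2f%% Se %.2f%% AUC %.2f%%\n",
              x$model, x$n_iterations, 100 * x$means$accuracy,
              100 * x$means$specificity, 100 * x$means$sensitivity,
              100 * x$means$auc))
  invisible(x)
}

#' Default hyperparameter grids
#'
#' Modest value lists over the supported hyperparameter names, meant as a
#' starting point for [grid_search()].
#'
#' @param name model name.
#' @return named list of value vectors.
#' @export
default_grid <- function(name = c("extra_trees", "random_forest", "svm")) {
  name <- match.arg(name)
  if (name == "svm") {
    list(C = c(1, 10, 100), kernel = c("linear", "radial"))
  } else {
    list(n_estimators = c(100, 300), max_features = c("sqrt", 0.2),
         min_samples_split = c(2, 4))
  }
}

#' Exhaustive grid search over hyperparameter combinations
#'
#' Evaluates every combination of the Cartesian product with the same
#' repeated-CV protocol (same fold partitions for every arm, so comparisons
#' are paired) and returns the combination with the highest mean
#' fraction-correct. Ties keep the earliest combination in enumeration order:
#' grid keys sorted alphabetically, values in the order listed.
#'
#' @param features,labels as in [evaluate_repeated_cv()].
#' @param model_name one of `"extra_trees"`, `"random_forest"`, `"svm"`.
#' @param grid named list of value vectors; names must be valid
#'   hyperparameters of the model.
#' @param cv a [cv_config()]; use a reduced `n_repeats` for wide grids.
#' @return list with `best_hyperparams`, `best_report` (the winning
#'   [evaluate_repeated_cv()] report) and `results` (one row per combination
#'   with its mean accuracy).
#' @export
grid_search <- function(features, labels, model_name, grid, cv = cv_config()) {
  if (length(grid) == 0 || is.null(names(grid)) || any(!nzchar(names(grid)))) {
    abort_ramanglu("`grid` must be a non-empty named list", class = "ramanglu_invalid_grid")
  }
  model_spec(model_name, hyperparams = lapply(grid, `[[`, 1)) # validates names
  ks <- sort(names(grid))
  combos <- expand.grid(rev(lapply(grid[ks], seq_along)))[, ks, drop = FALSE]
  best <- NULL
  results <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    hp <- lapply(ks, function(key) grid[[key]][[combos[i, key]]])
    names(hp) <- ks
    spec <- model_spec(model_name, hyperparams = hp,
                       seed = derive_seed(cv$seed, 9999))
    rep_i <- evaluate_repeated_cv(features, labels, spec, cv)
    results[[i]] <- data.frame(combo = i, accuracy = rep_i$means$accuracy,
                               t(vapply(hp, format, character(1))))
    if (is.null(best) || rep_i$means$accuracy > best$report$means$accuracy) {
      best <- list(hyperparams = hp, report = rep_i)
    }
  }
  list(best_hyperparams = best$hyperparams, best_report = best$report,
       results = do.call(rbind, results))
}
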