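tree_param_names <- c("n_estimators", "max_features", "max_depth",
                      "max_leaf_nodes", "min_samples_split", "min_samples_leaf")
svm_param_names <- c("C", "kernel", "gamma", "degree")

#' Specify a classifier
#'
#' Three model families are supported: `extra_trees` and `random_forest`
#' (ranger backends; Extra Trees uses fully random split points on the whole
#' sample without bootstrapping, Random Forest uses bootstrapped Gini trees)
#' and `svm` (e1071 backend with one-vs-rest decision scores and per-feature
#' global intensity centering/scaling fitted on the training fold).
#'
#' Tree models accept the hyperparameters `n_estimators`, `max_features`,
#' `max_depth`, `max_leaf_nodes`, `min_samples_split`, `min_samples_leaf`;
#' the SVM accepts `C`, `kernel`, `gamma`, `degree`. `max_leaf_nodes` is part
#' of the schema but only its default (unlimited, `NULL`) is supported: the
#' ranger backend has no leaf-count cap, and a finite value raises an error
#' rather than being silently ignored.
#'
#' @param name one of `"extra_trees"`, `"random_forest"`, `"svm"`.
#' @param hyperparams named list overriding defaults; unknown names error.
#' @param seed integer seed used when fitting (tree randomness).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(name = c("extra_trees", "random_forest", "svm"),
                       hyperparams = list(), seed = 1L) {
  name <- match.arg(name)
  valid <- if (name == "svm") svm_param_names else tree_param_names
  bad <- setdiff(names(hyperparams), valid)
  if (length(bad)) {
    abort_ramanglu(
      sprintf("invalid hyperparameter(s) for %s: %s (valid: %s)",
              name, paste(bad, collapse = ", "), paste(valid, collapse = ", ")),
      class = "ramanglu_invalid_grid")
  }
  defaults <- if (name == "svm") {
    list(C = 1, kernel = "radial", gamma = NULL, degree = 3)
  } else {
    list(n_estimators = 100, max_features = "sqrt", max_depth = NULL,
         max_leaf_nodes = NULL, min_samples_split = 2, min_samples_leaf = 1)
  }
  hp <- utils::modifyList(defaults, hyperparams, keep.null = TRUE)
  if (!is.null(hp$max_leaf_nodes)) {
    abort_ramanglu("`max_leaf_nodes` is schema-accepted but only NULL (unlimited) is supported by the tree backend",
                   class = "ramanglu_invalid_grid")
  }
  structure(list(name = name, hyperparams = hp, seed = as.integer(seed)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  hp <- vapply(x$hyperparams, function(v) if (is.null(v)) "NULL" else format(v), character(1))
  cat(sprintf("<model_spec> %s (%s)\n", x$name,
              paste(names(hp), hp, sep = "=", collapse = ", ")))
  invisible(x)
}

resolve_mtry <- function(max_features, p) {
  if (is.null(max_features)) return(p)
  if (is.character(max_features)) {
    return(switch(max_features,
                  sqrt = max(1L, floor(sqrt(p))),
                  log2 = max(1L, floor(log2(p))),
                  all = p,
                  abort_ramanglu(sprintf("unknown max_features '%s'", max_features),
                                 class = "ramanglu_invalid_grid")))
  }
  mf <- as.numeric(max_features)
  if (mf > 0 && mf < 1) max(1L, floor(mf * p)) else min(p, max(1L, as.integer(mf)))
}

normalize_kernel <- function(kernel) {
  switch(kernel,
         rbf = "radial", radial = "radial", linear = "linear",
         poly = "polynomial", polynomial = "polynomial", sigmoid = "sigmoid",
         abort_ramanglu(sprintf("unknown SVM kernel '%s'", kernel),
                        class = "ramanglu_invalid_grid"))
}

#' Fit a classifier on a feature matrix
#'
#' @param spec a [model_spec()].
#' @param x numeric matrix, samples by features.
#' @param y integer or factor class labels.
#' @param seed optional seed overriding `spec$seed` for this fit.
#' @return a fitted object of class `ramanglu_fit` usable with
#'   [predict_classifier()].
#' @export
fit_classifier <- function(spec, x, y, seed = NULL) {
  x <- as.matrix(x)
  classes <- sort(unique(as.integer(y)))
  yf <- factor(as.integer(y), levels = classes)
  seed <- as.integer(seed %||% spec$seed)
  hp <- spec$hyperparams
  if (spec$name %in% c("extra_trees", "random_forest")) {
    et <- spec$name == "extra_trees"
    colnames(x) <- paste0("f", seq_len(ncol(x)))
    fit <- ranger::ranger(
      x = x, y = yf,
      num.trees = as.integer(hp$n_estimators),
      mtry = resolve_mtry(hp$max_features, ncol(x)),
      min.node.size = as.integer(hp$min_samples_split),
      min.bucket = as.integer(hp$min_samples_leaf),
      max.depth = if (is.null(hp$max_depth)) 0L else as.integer(hp$max_depth),
      splitrule = if (et) "extratrees" else "gini",
      num.random.splits = 1L,
      replace = !et,
      sample.fraction = 1,
      probability = TRUE,
      num.threads = 1L, verbose = FALSE, seed = seed)
    structure(list(kind = "ranger", fit = fit, classes = classes),
              class = "ramanglu_fit")
  } else {
    # One global center/scale fitted on the training fold: spectral channels
    # share a physical unit (counts), and per-channel standardization would
    # inflate signal-free channels to the same weight as analyte bands.
    mu <- mean(x)
    sigma <- sd(as.vector(x))
    if (!is.finite(sigma) || sigma == 0) sigma <- 1
    xs <- (x - mu) / sigma
    gamma <- hp$gamma %||% (1 / ncol(x))
    kernel <- normalize_kernel(hp$kernel)
    multi <- e1071::svm(x = xs, y = yf, kernel = kernel, cost = hp$C,
                        gamma = gamma, degree = hp$degree, scale = FALSE)
    # one binary machine per class supplies the OvR decision score for AUC
    ovr <- lapply(classes, function(cl) {
      yb <- factor(ifelse(as.integer(as.character(yf)) == cl, "pos", "neg"),
                   levels = c("pos", "neg"))
      e1071::svm(x = xs, y = yb, kernel = kernel, cost = hp$C,
                 gamma = gamma, degree = hp$degree, scale = FALSE)
    })
    structure(list(kind = "svm", fit = multi, ovr = ovr, classes = classes,
                   center = mu, scale = sigma),
              class = "ramanglu_fit")
  }
}

#' Predict labels and per-class scores
#'
#' Tree models return out-of-forest vote fractions as scores; the SVM returns
#' one-vs-rest decision-function values (uncalibrated, rank-valid for AUC).
#' Predicted labels are the native multiclass predictions of each backend
#' (argmax vote fraction for the forests, pairwise voting for the SVM).
#'
#' @param object a `ramanglu_fit`.
#' @param newdata numeric matrix of samples to score.
#' @return list with `labels` (integer vector) and `scores` (matrix, one
#'   column per class, colnames = class codes).
#' @export
predict_classifier <- function(object, newdata) {
  newdata <- as.matrix(newdata)
  if (object$kind == "ranger") {
    colnames(newdata) <- paste0("f", seq_len(ncol(newdata)))
    prob <- predict(object$fit, data = newdata, num.threads = 1L,
                    verbose = FALSE)$predictions
    prob <- prob[, as.character(object$classes), drop = FALSE]
    labels <- object$classes[max.col(prob, ties.method = "first")]
    list(labels = labels, scores = prob)
  } else {
    xs <- (newdata - object$center) / object$scale
    labels <- as.integer(as.character(predict(object$fit, xs)))
    scores <- vapply(seq_along(object$classes), function(i) {
      dv <- attr(predict(object$ovr[[i]], xs, decision.values = TRUE),
                 "decision.values")
      # e1071 orients the sign toward the first class named in the column
      if (grepl("^pos/", colnames(dv)[1])) dv[, 1] else -dv[, 1]
    }, numeric(nrow(xs)))
    scores <- matrix(scores, nrow = nrow(xs),
                     dimnames = list(NULL, as.character(object$classes)))
    list(labels = labels, scores = scores)
  }
}
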