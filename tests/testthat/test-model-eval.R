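test_that("OvR metrics reproduce hand-computed confusion tables", {
  # 8-sample, 2-class case: class-1 table TP=3 FN=1 FP=1 TN=3
  m <- ovr_metrics(c(1, 1, 1, 1, 2, 2, 2, 2), c(1, 1, 2, 1, 2, 2, 1, 2))
  expect_identical(m$per_class$TP, c(3L, 3L))
  expect_identical(m$per_class$FN, c(1L, 1L))
  expect_identical(m$per_class$FP, c(1L, 1L))
  expect_identical(m$per_class$TN, c(3L, 3L))
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 0.75)
  expect_equal(m$macro_ovr_accuracy, 0.75)
  expect_equal(m$accuracy, 0.75)

  # 30-sample, 3-class case, frozen from direct enumeration of the tables
  true30 <- rep(1:3, each = 10)
  pred30 <- c(1, 1, 1, 1, 1, 1, 1, 2, 2, 3,
              2, 2, 2, 2, 2, 2, 1, 1, 3, 3,
              3, 3, 3, 3, 3, 3, 3, 3, 1, 2)
  m30 <- ovr_metrics(true30, pred30)
  expect_identical(m30$per_class$TP, c(7L, 6L, 8L))
  expect_identical(m30$per_class$FN, c(3L, 4L, 2L))
  expect_identical(m30$per_class$FP, c(3L, 3L, 3L))
  expect_identical(m30$per_class$TN, c(17L, 17L, 17L))
  expect_equal(m30$accuracy, 0.7)
  expect_equal(m30$macro_ovr_accuracy, 0.8)
  expect_equal(m30$specificity, 0.85)
  expect_equal(m30$sensitivity, 0.7)
})

test_that("perfect and totally wrong classifiers hit the metric extremes", {
  y <- rep(1:5, each = 3)
  scores <- vapply(1:5, function(cl) as.numeric(y == cl), numeric(length(y)))
  colnames(scores) <- 1:5
  perfect <- ovr_metrics(y, y, scores)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$auc, 1)

  flipped <- ovr_metrics(c(1, 1, 2, 2), c(2, 2, 1, 1))
  expect_equal(flipped$accuracy, 0)
  expect_equal(flipped$sensitivity, 0)
  expect_equal(flipped$specificity, 0)
})

test_that("rank-based AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(31, {
    for (i in 1:10) {
      labs <- sample(c(TRUE, FALSE), 40, replace = TRUE)
      if (length(unique(labs)) < 2) next
      sc <- round(rnorm(40), 1)  # rounding forces ties
      ours <- ramanglu:::auc_rank(sc, labs)
      ref <- as.numeric(pROC::auc(pROC::roc(labs, sc, quiet = TRUE,
                                            direction = "<")))
      expect_equal(ours, ref, tolerance = 1e-12)
    }
  })
})

test_that("micro-averaged TP total equals the number of correct predictions", {
  withr::with_seed(5, {
    for (i in 1:20) {
      true <- sample(1:4, 30, replace = TRUE)
      pred <- ifelse(runif(30) < 0.6, true, sample(1:4, 30, replace = TRUE))
      m <- suppressWarnings(ovr_metrics(true, pred))
      expect_identical(sum(m$per_class$TP), sum(true == pred))
    }
  })
})

test_that("OvR Se/Sp are invariant to relabeling among negative classes", {
  true <- rep(1:3, each = 8)
  pred <- c(rep(1, 6), 2, 3, rep(2, 5), 3, 3, 1, rep(3, 7), 2)
  m1 <- ovr_metrics(true, pred)
  swap <- function(v) ifelse(v == 2, 3L, ifelse(v == 3, 2L, v))
  m2 <- ovr_metrics(swap(true), swap(pred))
  expect_equal(m1$per_class[m1$per_class$class == 1, c("sensitivity", "specificity")],
               m2$per_class[m2$per_class$class == 1, c("sensitivity", "specificity")])
})

test_that("classes absent from the truth trigger a degenerate-class warning", {
  expect_warning(ovr_metrics(c(1, 1, 2, 2), c(1, 3, 2, 2)), "absent from the truth")
})

test_that("stratified repeated CV bookkeeping is exact", {
  y <- rep(1:10, each = 5)
  for (rep_i in 1:3) {
    fold <- ramanglu:::stratified_folds(y, 5, TRUE, seed = rep_i)
    expect_identical(sort(unique(fold)), 1:5)
    for (f in 1:5) expect_identical(unname(c(table(y[fold == f]))), rep(1L, 10))
    # each sample in exactly one test fold
    expect_identical(length(fold), 50L)
  }
})

test_that("CV reports are reproducible and correctly sized", {
  xy <- separable_xy()
  cv <- cv_config(k = 5, n_repeats = 3, seed = 17)
  r1 <- evaluate_repeated_cv(xy$x, xy$y, model_spec("extra_trees", seed = 2), cv)
  r2 <- evaluate_repeated_cv(xy$x, xy$y, model_spec("extra_trees", seed = 2), cv)
  expect_identical(r1$per_iteration, r2$per_iteration)
  expect_identical(r1$n_iterations, 15L)
  expect_identical(nrow(r1$per_iteration), 15L)
})

test_that("a widely separable two-class problem is solved by all models", {
  xy <- separable_xy()
  cv <- cv_config(k = 5, n_repeats = 2, seed = 3)
  for (m in c("extra_trees", "random_forest", "svm")) {
    r <- evaluate_repeated_cv(xy$x, xy$y, model_spec(m), cv)
    expect_equal(r$means$accuracy, 1)
    expect_equal(r$means$auc, 1)
  }
})

test_that("stratification requires k samples per class", {
  x <- matrix(rnorm(24), ncol = 2)
  y <- c(rep(1, 9), rep(2, 3))
  expect_error(evaluate_repeated_cv(x, y, model_spec("svm"),
                                    cv_config(k = 5, n_repeats = 1)),
               class = "ramanglu_stratification_error")
})

test_that("hyperparameter names are validated per model family", {
  expect_error(model_spec("svm", list(n_estimators = 10)),
               class = "ramanglu_invalid_grid")
  expect_error(model_spec("extra_trees", list(C = 1)),
               class = "ramanglu_invalid_grid")
  expect_error(model_spec("extra_trees", list(max_leaf_nodes = 16)),
               class = "ramanglu_invalid_grid")
  xy <- separable_xy()
  expect_error(grid_search(xy$x, xy$y, "svm", list(n_estimators = c(1, 2)),
                           cv_config(n_repeats = 1)),
               class = "ramanglu_invalid_grid")
})

test_that("grid search picks the arm that direct evaluation prefers", {
  # noisy separable problem: a 1-tree forest is measurably worse than 200 trees
  withr::with_seed(41, {
    x <- rbind(matrix(rnorm(60 * 8), ncol = 8),
               matrix(rnorm(60 * 8, mean = 0.8), ncol = 8))
    y <- rep(1:2, each = 60)
  })
  cv <- cv_config(k = 5, n_repeats = 2, seed = 11)
  gs <- grid_search(x, y, "extra_trees", list(n_estimators = c(1, 200)), cv)
  arm <- function(n) evaluate_repeated_cv(
    x, y, model_spec("extra_trees", list(n_estimators = n),
                     seed = ramanglu:::derive_seed(cv$seed, 9999)), cv)$means$accuracy
  expect_gt(arm(200), arm(1))
  expect_identical(gs$best_hyperparams$n_estimators, 200)
  expect_equal(gs$best_report$means$accuracy, arm(200))
  expect_identical(nrow(gs$results), 2L)

  # single-combination grid returns that combination
  gs1 <- grid_search(x, y, "svm", list(C = 10), cv_config(n_repeats = 1, seed = 1))
  expect_identical(gs1$best_hyperparams$C, 10)
})

test_that("grid enumeration is lexicographic over sorted keys", {
  xy <- separable_xy()
  cv <- cv_config(k = 5, n_repeats = 1, seed = 2)
  gs <- grid_search(xy$x, xy$y, "svm",
                    list(kernel = c("linear", "radial"), C = c(1, 10)), cv)
  # all arms tie at accuracy 1 -> first combination in sorted-key order wins
  expect_identical(gs$best_hyperparams, list(C = 1, kernel = "linear"))
})
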