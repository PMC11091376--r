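test_that("standardization uses training statistics only", {
  set.seed(81)
  train <- matrix(stats::rnorm(60, mean = 5, sd = 2), 20, 3)
  test <- matrix(stats::rnorm(15, mean = 5, sd = 2), 5, 3)
  out <- standardize(train, test)
  expect_lt(max(abs(colMeans(out$train))), 1e-12)
  # hand z-score of the test rows with train stats
  manual <- sweep(sweep(test, 2, colMeans(train)), 2,
                  apply(train, 2, stats::sd), "/")
  expect_equal(out$test, manual, tolerance = 1e-12)
  # already-standardized input passes through unchanged
  again <- standardize(out$train)
  expect_equal(again$train, out$train, tolerance = 1e-12)
  # constant columns become zeros with a warning
  const <- cbind(a = rep(3, 10), b = 1:10)
  expect_warning(res <- standardize(const), "constant")
  expect_equal(unname(res$train[, 1]), rep(0, 10))
})

test_that("k-fold partition is exact, balanced and seed-reproducible", {
  f1 <- kfold_split(100, 10, seed = 4)
  expect_equal(as.integer(table(f1)), rep(10L, 10))
  f2 <- kfold_split(103, 10, seed = 4)
  sizes <- as.integer(table(f2))
  expect_true(max(sizes) - min(sizes) <= 1L)
  expect_equal(sum(sizes), 103L)
  expect_identical(f2, kfold_split(103, 10, seed = 4))
  expect_false(identical(f1, kfold_split(100, 10, seed = 5)))
  expect_error(kfold_split(5, 10), "at least k")
})

test_that("classification metrics match a hand tally on a 12-record toy", {
  truth <- factor(c("a", "a", "a", "a", "b", "b", "b", "b", "c", "c", "c", "c"))
  pred <- factor(c("a", "a", "b", "c", "b", "b", "b", "a", "c", "c", "a", "b"),
                 levels = levels(truth))
  m <- classification_metrics(truth, pred)
  # hand tally: acc = 7/12; recall a 2/4, b 3/4, c 2/4 -> macro 7/12
  expect_equal(m$accuracy, 7 / 12)
  expect_equal(m$recall, mean(c(2 / 4, 3 / 4, 2 / 4)))
  # precision a 2/4, b 3/5, c 2/3; F per class = 2pr/(p+r)
  f_a <- 2 * (2 / 4) * (2 / 4) / (2 / 4 + 2 / 4)
  f_b <- 2 * (3 / 5) * (3 / 4) / (3 / 5 + 3 / 4)
  f_c <- 2 * (2 / 3) * (2 / 4) / (2 / 3 + 2 / 4)
  expect_equal(m$f_score, mean(c(f_a, f_b, f_c)))
  expect_equal(classification_metrics(truth, truth)$recall, 1)
})

test_that("rank-statistic AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(82)
  truth <- factor(sample(c("x", "y", "z"), 60, replace = TRUE))
  scores <- matrix(stats::runif(180), 60, 3, dimnames = list(NULL, c("x", "y", "z")))
  scores[cbind(seq_len(60), as.integer(truth))] <-
    scores[cbind(seq_len(60), as.integer(truth))] + 0.5
  m <- classification_metrics(truth, truth, scores)
  ref <- mean(vapply(levels(truth), function(cl)
    as.numeric(pROC::auc(pROC::roc(truth == cl, scores[, cl], quiet = TRUE,
                                   direction = "<"))), numeric(1)))
  expect_equal(m$auc, ref, tolerance = 1e-9)
})

test_that("scores unrelated to truth give chance-level AUC", {
  set.seed(83)
  truth <- factor(rep(c("p", "q"), each = 250))
  scores <- matrix(stats::runif(1000), 500, 2, dimnames = list(NULL, c("p", "q")))
  m <- classification_metrics(truth, sample(truth), scores)
  expect_lt(abs(m$auc - 0.5), 0.07)
})

test_that("regression metrics match manual arithmetic and conventions", {
  truth <- c(1, 2, 3, 4, 5)
  pred <- c(1.1, 1.9, 3.2, 3.8, 5.1)
  m <- regression_metrics(truth, pred)
  expect_equal(m$mse, mean((truth - pred)^2), tolerance = 1e-12)
  expect_equal(m$mae, mean(abs(truth - pred)), tolerance = 1e-12)
  expect_equal(m$r2, 1 - sum((truth - pred)^2) / sum((truth - 3)^2),
               tolerance = 1e-12)
  expect_equal(regression_metrics(truth, truth)$r2, 1)
  expect_equal(regression_metrics(truth, rep(mean(truth), 5))$r2, 0)
  # zero-variance truth: R2 = 1 only for exact prediction, else undefined
  expect_equal(regression_metrics(rep(2, 5), rep(2, 5))$r2, 1)
  flagged <- regression_metrics(rep(2, 5), c(2, 2, 2, 2, 3))
  expect_true(is.na(flagged$r2))
  expect_false(flagged$r2_defined)
})

test_that("cross-validation partitions exactly and nails separable data", {
  set.seed(84)
  x <- rbind(matrix(stats::rnorm(100, mean = 0), 50, 2),
             matrix(stats::rnorm(100, mean = 8), 50, 2))
  y <- factor(rep(c("lo", "hi"), each = 50))
  cv <- cross_validate(x, y, knn_classifier(3), k = 10, seed = 6,
                       task = "classification")
  expect_equal(cv$mean[["accuracy"]], 1.0)
  # partition exactness: union of folds is everything, disjoint by design
  expect_equal(sort(unique(cv$folds)), 1:10)
  expect_equal(length(cv$folds), 100L)
  # constant-target regression with an exact predictor
  xr <- matrix(stats::rnorm(80), 40, 2)
  cvr <- cross_validate(xr, rep(5, 40), ridge_regressor(0), k = 5, seed = 6,
                        task = "regression")
  expect_lt(cvr$mean[["mse"]], 1e-12)
  expect_equal(cvr$mean[["r2"]], 1)
})

test_that("shuffled labels score at the class prior (leakage guard)", {
  set.seed(85)
  n <- 300
  x <- matrix(stats::rnorm(2 * n), n, 2)
  y <- factor(sample(rep(c("a", "b"), each = n / 2)))  # labels independent of x
  cv <- cross_validate(x, y, knn_classifier(5), k = 10, seed = 7,
                       task = "classification")
  prior <- 0.5
  sigma <- sqrt(prior * (1 - prior) / n)
  expect_lt(abs(cv$mean[["accuracy"]] - prior), 3 * sigma + 0.05)
})

test_that("grid search selects the generating penalty and breaks ties first-in-grid", {
  set.seed(86)
  x <- matrix(stats::rnorm(300), 100, 3)
  y <- as.numeric(x %*% c(2, -1, 0.5) + stats::rnorm(100, sd = 0.05))
  gs <- grid_search(x, y, ridge_regressor,
                    data.frame(lambda = c(1e-6, 1, 1000)), k = 5, seed = 8,
                    task = "regression")
  expect_equal(gs$best_hyperparameters$lambda, 1e-6)
  # exhaustive verification: best has the minimum mean CV MSE
  mses <- vapply(gs$all_results, function(r) r$mean[["mse"]], numeric(1))
  expect_equal(gs$best_result$mean[["mse"]], min(mses))
  # single-point grid returns that point; ties go to the first entry
  one <- grid_search(x, y, ridge_regressor, data.frame(lambda = 0.5),
                     k = 5, seed = 8, task = "regression")
  expect_equal(one$best_hyperparameters$lambda, 0.5)
  tie <- grid_search(x, y, ridge_regressor,
                     data.frame(lambda = c(0.5, 0.5)), k = 5, seed = 8,
                     task = "regression")
  expect_equal(which.max(tie$score), 1L)
  expect_error(grid_search(x, y, ridge_regressor, list(), k = 5, seed = 8,
                           task = "regression"), "non-empty")
})
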