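#' Standardize feature columns with training-fold statistics
#'
#' Column-wise z-scoring. Statistics (mean, sd) are computed on the training
#' rows only and applied unchanged to any test rows, so no information leaks
#' from held-out data. Constant columns pass through as zeros with a
#' warning.
#'
#' @param train numeric matrix/data.frame of training features.
#' @param test optional matrix of rows to transform with the training stats.
#' @param stats optional precomputed list (`center`, `scale`) to reuse.
#' @return list with `train`, `test` (or `NULL`) and `stats`.
#' @export
standardize <- function(train, test = NULL, stats = NULL) {
  train <- as.matrix(train); storage.mode(train) <- "double"
  if (is.null(stats)) {
    ctr <- colMeans(train)
    scl <- apply(train, 2L, stats::sd)
    if (any(scl == 0)) {
      warning("constant feature column(s) standardized to zero: ",
              paste(colnames(train)[scl == 0], collapse = ", "))
      scl[scl == 0] <- 1
    }
    stats <- list(center = ctr, scale = scl)
  }
  z <- function(x) sweep(sweep(as.matrix(x), 2L, stats$center), 2L,
                         stats$scale, "/")
  list(train = z(train), test = if (is.null(test)) NULL else z(test),
       stats = stats)
}

#' Shuffled k-fold partition
#'
#' @param n number of records.
#' @param k number of folds (default 10).
#' @param seed RNG seed; the same seed reproduces the same assignment.
#' @return integer vector of fold labels 1..k, sizes differing by at most 1.
#' @export
kfold_split <- function(n, k = 10L, seed = 1L) {
  if (n < k) stop("need at least k records (n = ", n, ", k = ", k, ")")
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

#' Built-in reference estimators
#'
#' Two simple estimators satisfying the pluggable-estimator contract
#' (`fit(x, y)` returning a model with `predict(model, x)` and optionally
#' `predict_scores(model, x)`): a k-nearest-neighbour classifier (majority
#' vote over standardized features, per-class vote fractions as scores) and
#' a closed-form ridge regressor. Any estimator exposing the same contract
#' — including external learners — plugs into [cross_validate] and
#' [grid_search] the same way.
#'
#' @param k number of neighbours (classifier).
#' @return list of class `hm_estimator` with elements `fit`,
#'   `predict`, `predict_scores` (classifier only) and `hyperparameters`.
#' @export
knn_classifier <- function(k = 5L) {
  structure(list(
    hyperparameters = list(k = k),
    fit = function(x, y) list(x = as.matrix(x), y = factor(y), k = k),
    predict = function(model, x) {
      class::knn(model$x, as.matrix(x), model$y, k = model$k)
    },
    predict_scores = function(model, x) {
      x <- as.matrix(x)
      lev <- levels(model$y)
      out <- matrix(0, nrow(x), length(lev), dimnames = list(NULL, lev))
      for (i in seq_len(nrow(x))) {
        d <- sqrt(colSums((t(model$x) - x[i, ])^2))
        nb <- model$y[order(d)[seq_len(model$k)]]
        out[i, ] <- as.numeric(table(nb)[lev]) / model$k
      }
      out[is.na(out)] <- 0
      out
    }), class = "hm_estimator")
}

#' @rdname knn_classifier
#' @param lambda ridge penalty (regressor), >= 0.
#' @export
ridge_regressor <- function(lambda = 1e-3) {
  structure(list(
    hyperparameters = list(lambda = lambda),
    fit = function(x, y) {
      x <- cbind(1, as.matrix(x))
      p <- ncol(x)
      pen <- diag(lambda, p); pen[1L, 1L] <- 0   # intercept unpenalized
      list(beta = solve(crossprod(x) + pen, crossprod(x, y)))
    },
    predict = function(model, x) {
      as.numeric(cbind(1, as.matrix(x)) %*% model$beta)
    }), class = "hm_estimator")
}

#' Classification metrics: accuracy, macro recall, macro F-score, macro AUC
#'
#' Recall and F-score are macro-averaged over the classes present in the
#' truth; classes absent from the truth are excluded from the macro average
#' with a warning. AUC is the mean over present classes of the one-vs-rest
#' rank-statistic (Mann-Whitney) area computed from per-class scores, and is
#' `NA` when scores are not supplied.
#'
#' @param truth factor (or coercible) of true classes.
#' @param predicted factor of predicted classes.
#' @param scores optional numeric matrix of per-class scores, columns named
#'   by class.
#' @return named list: `accuracy`, `recall`, `f_score`, `auc`.
#' @export
classification_metrics <- function(truth, predicted, scores = NULL) {
  lev <- union(levels(factor(truth)), levels(factor(predicted)))
  truth <- factor(truth, levels = lev)
  predicted <- factor(predicted, levels = lev)
  if (length(truth) != length(predicted)) stop("length mismatch")
  present <- lev[lev %in% unique(as.character(truth))]
  if (length(present) < 2L) stop("need at least 2 classes in truth")
  if (length(present) < length(lev))
    warning("classes absent from truth excluded from macro averages: ",
            paste(setdiff(lev, present), collapse = ", "))
  acc <- mean(truth == predicted)
  per <- vapply(present, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    fp <- sum(truth != cl & predicted == cl)
    rec <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    f <- if (is.na(rec) || prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(rec, f)
  }, numeric(2L))
  auc <- NA_real_
  if (!is.null(scores)) {
    aucs <- vapply(present, function(cl) {
      pos <- truth == cl
      s <- scores[, cl]
      r <- rank(s)
      n1 <- sum(pos); n0 <- sum(!pos)
      (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }, numeric(1L))
    auc <- mean(aucs)
  }
  list(accuracy = acc, recall = mean(per[1L, ]), f_score = mean(per[2L, ]),
       auc = auc)
}

#' Regression metrics: R-squared, MSE, MAE
#'
#' `R2 = 1 - SS_res / SS_tot`. For a zero-variance truth the ratio is
#' undefined; by documented convention the result is 1 when the predictions
#' are exact and `NA` (with `r2_defined = FALSE`) otherwise.
#'
#' @param truth,predicted aligned numeric vectors, length >= 2.
#' @return named list: `r2`, `mse`, `mae`, `r2_defined`.
#' @export
regression_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted) || length(truth) < 2L)
    stop("need aligned vectors of length >= 2")
  res <- truth - predicted
  sst <- sum((truth - mean(truth))^2)
  if (sst == 0) {
    exact <- all(res == 0)
    return(list(r2 = if (exact) 1 else NA_real_, mse = mean(res^2),
                mae = mean(abs(res)), r2_defined = exact))
  }
  list(r2 = 1 - sum(res^2) / sst, mse = mean(res^2), mae = mean(abs(res)),
       r2_defined = TRUE)
}

#' Cross-validated evaluation of an estimator
#'
#' Shuffled k-fold cross-validation: for each fold, features are
#' standardized with statistics from the training rows only, the estimator
#' is fitted on the k-1 training folds and evaluated on the held-out fold.
#' Per-fold metrics and their mean and sd are reported.
#'
#' @param features numeric matrix/data.frame.
#' @param targets response vector (factor for classification).
#' @param estimator an estimator from e.g. [knn_classifier] or
#'   [ridge_regressor], or any list with the same contract.
#' @param k folds (default 10).
#' @param seed fold-assignment seed.
#' @param task `"classification"` or `"regression"`.
#' @return object of class `cv_result`: `per_fold` data.frame, `mean`,
#'   `sd`, `folds`, `seed`.
#' @export
cross_validate <- function(features, targets, estimator, k = 10L, seed = 1L,
                           task = c("classification", "regression")) {
  task <- match.arg(task)
  features <- as.matrix(features)
  folds <- kfold_split(nrow(features), k = k, seed = seed)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    std <- suppressWarnings(standardize(features[tr, , drop = FALSE],
                                        features[te, , drop = FALSE]))
    model <- tryCatch(estimator$fit(std$train, targets[tr]),
                      error = function(e) stop("estimator failed on fold ",
                                               f, ": ", conditionMessage(e)))
    pred <- estimator$predict(model, std$test)
    if (task == "classification") {
      scores <- if (!is.null(estimator$predict_scores))
        estimator$predict_scores(model, std$test) else NULL
      mt <- suppressWarnings(
        classification_metrics(targets[te], pred, scores))
      rows[[f]] <- data.frame(fold = f, accuracy = mt$accuracy,
                              recall = mt$recall, f_score = mt$f_score,
                              auc = mt$auc)
    } else {
      mt <- regression_metrics(as.numeric(targets[te]), as.numeric(pred))
      rows[[f]] <- data.frame(fold = f, r2 = mt$r2, mse = mt$mse,
                              mae = mt$mae)
    }
  }
  per <- do.call(rbind, rows)
  mets <- setdiff(names(per), "fold")
  structure(list(per_fold = per,
                 mean = colMeans(per[mets], na.rm = TRUE),
                 sd = apply(per[mets], 2L, stats::sd, na.rm = TRUE),
                 folds = folds, seed = seed, task = task),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", max(x$folds), "-fold ", x$task, "\n", sep = "")
  print(round(x$mean, 4L))
  invisible(x)
}

#' Exhaustive grid search over estimator hyperparameters
#'
#' Evaluates every hyperparameter combination with [cross_validate] and
#' returns the best: maximum mean accuracy for classification, minimum mean
#' MSE for regression. Ties are broken by first-in-grid order.
#'
#' @param features,targets,k,seed,task as in [cross_validate].
#' @param estimator_factory function(...) returning an estimator for one
#'   hyperparameter combination (e.g. [knn_classifier]).
#' @param grid data.frame (or list of lists) of hyperparameter combinations,
#'   one row/element per combination; must be non-empty.
#' @return list with `best_hyperparameters`, `best_result` (a `cv_result`),
#'   `all_results` and the selection `score` per combination.
#' @export
grid_search <- function(features, targets, estimator_factory, grid,
                        k = 10L, seed = 1L,
                        task = c("classification", "regression")) {
  task <- match.arg(task)
  if (is.data.frame(grid)) grid <- lapply(seq_len(nrow(grid)), function(i)
    as.list(grid[i, , drop = FALSE]))
  if (!length(grid)) stop("hyperparameter grid must be non-empty")
  results <- lapply(grid, function(hp)
    cross_validate(features, targets, do.call(estimator_factory, hp),
                   k = k, seed = seed, task = task))
  score <- vapply(results, function(r)
    if (task == "classification") r$mean[["accuracy"]] else -r$mean[["mse"]],
    numeric(1L))
  best <- which.max(score)        # which.max takes the first of tied maxima
  list(best_hyperparameters = grid[[best]], best_result = results[[best]],
       all_results = results, score = score)
}
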