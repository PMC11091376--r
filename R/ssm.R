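#' Rigidly align landmark configurations
#'
#' Generalized Procrustes superimposition without scaling: each configuration
#' is translated to a common centroid and rotated (Kabsch, via SVD) onto an
#' iteratively refined mean shape. Size is deliberately retained — stature and
#' BMI drive head size, so scale is signal for the shape regression, not
#' nuisance. `mode = "none"` returns the input unchanged.
#'
#' @param landmark_arrays list of m x 3 matrices sharing the same landmark
#'   order.
#' @param mode `"rigid_procrustes"` or `"none"`.
#' @param max_iter,tol convergence controls for the mean-shape iteration.
#' @return list with `aligned` (list of m x 3 matrices) and `transforms`
#'   (list of `list(rotation, translation)` mapping input to aligned).
#' @export
align_landmarks <- function(landmark_arrays, mode = c("rigid_procrustes", "none"),
                            max_iter = 20L, tol = 1e-10) {
  mode <- match.arg(mode)
  m <- nrow(landmark_arrays[[1L]])
  if (any(vapply(landmark_arrays, nrow, 1L) != m))
    stop("all landmark arrays must share the same landmark count")
  if (mode == "none") {
    return(list(aligned = landmark_arrays,
                transforms = replicate(length(landmark_arrays),
                  list(rotation = diag(3), translation = c(0, 0, 0)),
                  simplify = FALSE)))
  }
  if (m < 3L) stop("rigid alignment needs at least 3 landmarks")
  centered <- lapply(landmark_arrays, function(a) sweep(a, 2L, colMeans(a)))
  translations <- lapply(landmark_arrays, colMeans)
  for (a in centered) {
    d <- svd(a, nu = 0, nv = 0)$d
    if (d[2L] / d[1L] < 1e-12)   # rank <= 1: all points on one line
      stop("collinear landmark configuration: rotation is ill-posed")
  }
  rots <- replicate(length(centered), diag(3), simplify = FALSE)
  aligned <- centered
  ref <- aligned[[1L]]
  for (it in seq_len(max_iter)) {
    for (i in seq_along(aligned)) {
      r <- kabsch_rotation(centered[[i]], ref)
      rots[[i]] <- r
      aligned[[i]] <- centered[[i]] %*% r
    }
    new_ref <- Reduce(`+`, aligned) / length(aligned)
    if (sqrt(sum((new_ref - ref)^2)) < tol) { ref <- new_ref; break }
    ref <- new_ref
  }
  list(aligned = aligned,
       transforms = Map(function(r, t) list(rotation = r, translation = -t),
                        rots, translations))
}

# rotation R minimising ||X R - Y||_F over proper rotations (Kabsch)
kabsch_rotation <- function(x, y) {
  s <- svd(crossprod(x, y))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Fit a PCA landmark shape model
#'
#' Stacks each m x 3 landmark configuration into a 3m-vector and performs
#' principal component analysis across subjects. The model retains the mean
#' shape, the first `k` orthonormal modes, the per-subject component scores
#' and the explained variance per mode.
#'
#' @param landmark_arrays list of n aligned m x 3 matrices.
#' @param k number of components; must satisfy `k <= min(n - 1, 3 m)`.
#' @param alignment flag recorded in the model (`"none"` or `"procrustes"`).
#' @return An object of class `shape_model` with fields `mean_shape` (3m),
#'   `basis` (3m x k), `scores` (n x k), `explained_variance` (k),
#'   `n_components`, `n_subjects`, `n_landmarks`, `alignment`.
#' @export
fit_pca <- function(landmark_arrays, k, alignment = "none") {
  n <- length(landmark_arrays)
  if (n < 2L) stop("need at least 2 subjects")
  m <- nrow(landmark_arrays[[1L]])
  x <- t(vapply(landmark_arrays, function(a) as.numeric(t(a)), numeric(3L * m)))
  if (k < 1L || k > min(n - 1L, 3L * m))
    stop("k must be in [1, min(n-1, 3m)] = [1, ", min(n - 1L, 3L * m), "]")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  structure(list(
    mean_shape = as.numeric(pc$center),
    basis = pc$rotation[, seq_len(k), drop = FALSE],
    scores = pc$x[, seq_len(k), drop = FALSE],
    explained_variance = pc$sdev[seq_len(k)]^2,
    n_components = k, n_subjects = n, n_landmarks = m,
    alignment = alignment), class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  ev <- x$explained_variance
  cat("<shape_model> ", x$n_subjects, " subjects, ", x$n_landmarks,
      " landmarks, k = ", x$n_components, "\n", sep = "")
  cat("  variance captured by retained modes: ",
      sprintf("%.1f%%", 100 * sum(ev) / max(sum(ev), .Machine$double.eps)),
      " of retained total; leading mode ",
      sprintf("%.3g", ev[1L]), "\n", sep = "")
  invisible(x)
}

#' Regress shape-model scores on subject characteristics
#'
#' Fits the linear characteristic model: each retained principal-component
#' score is regressed on (gender, age, height, BMI). The printed form of the
#' model has no intercept; because PC scores are mean-centred by
#' construction, the characteristics are centred (and optionally unit-scaled)
#' before the per-component least-squares solve, which makes the
#' intercept-free form well-posed.
#'
#' @param model a fitted [fit_pca] `shape_model`.
#' @param characteristics n x 4 data.frame or matrix with columns gender,
#'   age, height, bmi, rows aligned with the model's subjects.
#' @param scale also divide each centred characteristic by its standard
#'   deviation (default `FALSE`: centring only).
#' @return An object of class `characteristic_regression` with `A` (k x 4
#'   coefficients on the centred/scaled scale), `characteristic_means`,
#'   `characteristic_scales`, `residuals` (n x k), `fit_r2` (k).
#' @export
fit_characteristic_regression <- function(model, characteristics,
                                          scale = FALSE) {
  z <- as.matrix(characteristics[, c("gender", "age", "height", "bmi")])
  storage.mode(z) <- "double"
  if (nrow(z) != model$n_subjects)
    stop("characteristics rows must align with model scores")
  if (nrow(z) <= 4L) stop("need more than 4 subjects to fit 4 coefficients")
  mu <- colMeans(z)
  sc <- if (scale) apply(z, 2L, stats::sd) else rep(1, 4L)
  const <- which(apply(z, 2L, function(v) max(v) - min(v)) == 0)
  if (length(const))
    stop("rank-deficient characteristic matrix: constant column '",
         colnames(z)[const[1L]], "'")
  zc <- sweep(sweep(z, 2L, mu), 2L, sc, "/")
  fit <- stats::lm.fit(zc, model$scores)
  coefs <- fit$coefficients               # 4 x k
  if (anyNA(coefs))
    stop("rank-deficient characteristic matrix: collinear column '",
         colnames(z)[which(apply(is.na(coefs), 1L, any))[1L]], "'")
  res <- model$scores - zc %*% coefs
  sst <- colSums(model$scores^2)
  r2 <- 1 - colSums(res^2) / ifelse(sst > 0, sst, 1)
  r2[sst == 0] <- 1
  structure(list(A = t(coefs), characteristic_means = mu,
                 characteristic_scales = sc, residuals = res, fit_r2 = r2,
                 scaled = scale),
            class = "characteristic_regression")
}

#' @export
print.characteristic_regression <- function(x, ...) {
  cat("<characteristic_regression> k = ", nrow(x$A),
      " components on 4 characteristics; mean R2 = ",
      sprintf("%.3f", mean(x$fit_r2)), "\n", sep = "")
  invisible(x)
}

#' Predict a landmark configuration from subject characteristics
#'
#' Applies the fitted shape regression: predicted scores are
#' `A %*% (centred characteristics)` and the landmark configuration is
#' `mean_shape + basis %*% scores`, reshaped m x 3. Characteristics outside
#' the training range raise an extrapolation warning, not an error.
#'
#' @param model a `shape_model`.
#' @param regression a matching `characteristic_regression`.
#' @param chars a one-row data.frame (or [subject_characteristics]) with
#'   gender, age, height, bmi; or an n-row table for batch prediction.
#' @param training_range optional 2 x 4 matrix (min/max per characteristic)
#'   used for the extrapolation warning.
#' @return m x 3 matrix, or a list of matrices for batch input.
#' @export
predict_landmarks <- function(model, regression, chars,
                              training_range = NULL) {
  z <- as.matrix(as.data.frame(chars)[, c("gender", "age", "height", "bmi")])
  storage.mode(z) <- "double"
  if (!is.null(training_range)) {
    lo <- training_range[1L, ]; hi <- training_range[2L, ]
    if (any(t(z) < lo) || any(t(z) > hi))
      warning("characteristics outside the training range: extrapolating")
  }
  zc <- sweep(sweep(z, 2L, regression$characteristic_means), 2L,
              regression$characteristic_scales, "/")
  scores <- zc %*% t(regression$A)            # n x k
  flat <- matrix(model$mean_shape, nrow(z), length(model$mean_shape),
                 byrow = TRUE) + scores %*% t(model$basis)
  out <- lapply(seq_len(nrow(z)), function(i)
    matrix(flat[i, ], ncol = 3L, byrow = TRUE))
  if (nrow(z) == 1L) out[[1L]] else out
}

#' Full-factorial characteristic sampling grid
#'
#' Evenly spaced design grid over the four characteristics, used to
#' homogenise the characteristic distribution before batch landmark
#' prediction. The default layout — 2 gender levels x 5 ages x 5 heights x
#' 4 BMI levels — yields 200 design points.
#'
#' @param age_range,height_range,bmi_range numeric length-2 ranges
#'   (years, m, kg/m^2).
#' @param counts named integer vector with entries `age`, `height`, `bmi`
#'   (number of evenly spaced levels per axis; endpoints included when the
#'   count exceeds 1, the midpoint for a count of 1).
#' @param gender_levels gender codes to cross in (default both 0 and 1).
#' @param total optional required total; an error lists the achievable
#'   per-axis factorizations if the product of counts does not match.
#' @return data.frame of `subject_characteristics` rows (gender, age,
#'   height, bmi), one per grid point.
#' @export
sample_design_grid <- function(age_range = c(10, 90),
                               height_range = c(1.45, 1.95),
                               bmi_range = c(15, 35),
                               counts = c(age = 5L, height = 5L, bmi = 4L),
                               gender_levels = c(0, 1),
                               total = NULL) {
  if (any(counts < 1L)) stop("counts must be >= 1 per axis")
  lev <- function(range, n) if (n == 1L) mean(range) else
    seq(range[1L], range[2L], length.out = n)
  grid <- expand.grid(gender = gender_levels,
                      age = lev(age_range, counts[["age"]]),
                      height = lev(height_range, counts[["height"]]),
                      bmi = lev(bmi_range, counts[["bmi"]]),
                      KEEP.OUT.ATTRS = FALSE)
  if (!is.null(total) && nrow(grid) != total)
    stop("grid of ", nrow(grid), " points cannot meet requested total ",
         total, "; valid factorizations must satisfy genders*age*height*bmi = ",
         total)
  structure(grid[, c("gender", "age", "height", "bmi")],
            class = c("subject_characteristics", "data.frame"))
}
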