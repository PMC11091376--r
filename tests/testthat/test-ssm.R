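test_that("rigid alignment superimposes rotated copies and preserves size", {
  set.seed(41)
  base <- random_landmarks(12)
  r <- random_rotation()
  rotated <- base %*% r + matrix(c(10, -5, 3), 12, 3, byrow = TRUE)
  out <- align_landmarks(list(base, rotated), mode = "rigid_procrustes")
  expect_lt(max(abs(out$aligned[[1]] - out$aligned[[2]])), 1e-9)

  # identical arrays: zero inter-subject variance after alignment
  out2 <- align_landmarks(list(base, base, base), mode = "rigid_procrustes")
  v <- Reduce(`+`, lapply(out2$aligned, function(a)
    (a - Reduce(`+`, out2$aligned) / 3)^2))
  expect_lt(max(v), 1e-18)

  # scale differences are signal and must survive alignment
  scaled <- base * 1.1
  out3 <- align_landmarks(list(base, scaled), mode = "rigid_procrustes")
  csize <- function(a) sqrt(sum(sweep(a, 2, colMeans(a))^2))
  expect_equal(csize(out3$aligned[[2]]) / csize(out3$aligned[[1]]), 1.1,
               tolerance = 1e-9)

  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(align_landmarks(list(line, line), mode = "rigid_procrustes"),
               "collinear")
})

test_that("PCA of a single displacement direction matches a direct eigensolve", {
  set.seed(40)
  m <- 6L
  base <- random_landmarks(m)
  dir <- stats::rnorm(3 * m); dir <- dir / sqrt(sum(dir^2))
  amp <- c(-2, 0.5, 1.5)
  subj <- lapply(amp, function(a)
    base + matrix(a * dir, ncol = 3, byrow = TRUE))
  model <- fit_pca(subj, k = 2L)
  # independent oracle: eigen-decomposition of the 3m x 3m covariance
  x <- t(vapply(subj, function(s) as.numeric(t(s)), numeric(3 * m)))
  cov <- stats::cov(x)
  ev <- eigen(cov, symmetric = TRUE)
  expect_equal(model$explained_variance[1], ev$values[1], tolerance = 1e-9)
  expect_lt(model$explained_variance[2], 1e-18)
  # scores match projection onto the leading eigenvector (up to sign)
  sc <- sweep(x, 2, colMeans(x)) %*% ev$vectors[, 1]
  expect_equal(abs(model$scores[, 1]), abs(as.numeric(sc)), tolerance = 1e-9)
})

test_that("identical subjects give zero variance and zero scores", {
  set.seed(46)
  base <- random_landmarks(5)
  model <- fit_pca(list(base, base, base, base), k = 3L)
  expect_lt(max(abs(model$scores)), 1e-9)
  expect_lt(max(model$explained_variance), 1e-18)
})

test_that("pca basis is orthonormal, scores centred, and k range enforced", {
  set.seed(42)
  pop <- generate_population(population_spec(n_subjects = 20L,
                                             n_landmarks = 10L, seed = 42L))
  model <- fit_pca(pop$landmarks, k = 8L)
  gram <- crossprod(model$basis)
  expect_lt(max(abs(gram - diag(8))), 1e-8)
  expect_lt(max(abs(colMeans(model$scores))), 1e-8)
  expect_error(fit_pca(pop$landmarks, k = 25L), "k must be")
  # full-rank reconstruction identity
  full <- fit_pca(pop$landmarks, k = 19L)
  recon <- matrix(full$mean_shape, 20, 30, byrow = TRUE) +
    full$scores %*% t(full$basis)
  x <- t(vapply(pop$landmarks, function(a) as.numeric(t(a)), numeric(30)))
  expect_lt(max(abs(recon - x)), 1e-8)
})

test_that("characteristic regression matches independent normal equations", {
  set.seed(43)
  n <- 5L
  chars <- data.frame(gender = c(0, 1, 0, 1, 1), age = c(20, 35, 50, 65, 80),
                      height = c(1.55, 1.7, 1.62, 1.8, 1.75),
                      bmi = c(18, 24, 27, 22, 31))
  lms <- lapply(1:n, function(i) random_landmarks(4))
  model <- fit_pca(lms, k = 1L)
  reg <- fit_characteristic_regression(model, chars)
  # brute-force normal equations on the centred design
  z <- sweep(as.matrix(chars), 2, colMeans(as.matrix(chars)))
  beta <- solve(crossprod(z), crossprod(z, model$scores[, 1]))
  expect_equal(as.numeric(reg$A[1, ]), as.numeric(beta), tolerance = 1e-8)
  expect_lt(max(abs(colMeans(reg$residuals))), 1e-8)
})

test_that("zero scores give zero coefficients; constant columns are named", {
  set.seed(47)
  base <- random_landmarks(5)
  model <- fit_pca(list(base, base, base, base, base, base), k = 2L)
  chars <- data.frame(gender = c(0, 1, 0, 1, 0, 1),
                      age = c(20, 35, 50, 65, 28, 44),
                      height = c(1.55, 1.7, 1.62, 1.8, 1.75, 1.68),
                      bmi = c(18, 24, 27, 22, 31, 26))
  reg <- fit_characteristic_regression(model, chars)
  expect_lt(max(abs(reg$A)), 1e-9)
  expect_lt(max(abs(reg$residuals)), 1e-9)
  chars$bmi <- 25
  expect_error(fit_characteristic_regression(model, chars), "bmi")
})

test_that("noiseless synthetic population is recovered exactly", {
  pop <- generate_population(population_spec(noise_sigma = 0, seed = 7L))
  model <- fit_pca(pop$landmarks, k = 40L)
  reg <- fit_characteristic_regression(model, pop$characteristics)
  # compare full linear maps characteristic -> landmark space (basis-free)
  fitted_map <- model$basis %*% reg$A
  true_map_raw <- sweep(pop$true_map, 2, pop$char_scales, "/")
  relerr <- norm(fitted_map - true_map_raw, "F") / norm(true_map_raw, "F")
  expect_lt(relerr, 1e-8)
  # prediction at a training subject reproduces its landmarks
  pred <- predict_landmarks(model, reg, pop$characteristics[3, ])
  expect_lt(max(abs(pred - pop$landmarks[[3]])), 1e-6)
})

test_that("prediction at the characteristic mean returns the mean shape", {
  set.seed(44)
  pop <- generate_population(population_spec(n_subjects = 15L,
                                             n_landmarks = 8L, seed = 44L))
  model <- fit_pca(pop$landmarks, k = 5L)
  reg <- fit_characteristic_regression(model, pop$characteristics)
  mu <- as.data.frame(t(colMeans(as.matrix(pop$characteristics))))
  pred <- predict_landmarks(model, reg, mu)
  expect_equal(as.numeric(t(pred)), model$mean_shape, tolerance = 1e-9)
})

test_that("parameter recovery error decreases with landmark noise", {
  relerr_at <- function(sig) {
    pop <- generate_population(population_spec(noise_sigma = sig, seed = 8L))
    model <- fit_pca(pop$landmarks, k = 40L)
    reg <- fit_characteristic_regression(model, pop$characteristics)
    true_raw <- sweep(pop$true_map, 2, pop$char_scales, "/")
    norm(model$basis %*% reg$A - true_raw, "F") / norm(true_raw, "F")
  }
  errs <- vapply(c(2, 0.2, 0), relerr_at, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.01)
})

test_that("translating all subjects moves only the mean shape", {
  set.seed(45)
  pop <- generate_population(population_spec(n_subjects = 10L,
                                             n_landmarks = 6L, seed = 45L))
  shift <- c(12, -7, 30)
  shifted <- lapply(pop$landmarks, function(a)
    sweep(a, 2, shift, "+"))
  m1 <- fit_pca(pop$landmarks, k = 4L)
  m2 <- fit_pca(shifted, k = 4L)
  expect_equal(abs(m1$scores), abs(m2$scores), tolerance = 1e-8)
  r1 <- fit_characteristic_regression(m1, pop$characteristics)
  r2 <- fit_characteristic_regression(m2, pop$characteristics)
  expect_equal(abs(r1$A), abs(r2$A), tolerance = 1e-8)
  delta <- matrix(m2$mean_shape - m1$mean_shape, ncol = 3, byrow = TRUE)
  expect_equal(delta, matrix(shift, nrow(delta), 3, byrow = TRUE),
               tolerance = 1e-9)
})

test_that("design grid defaults to 200 homogenized points", {
  grid <- sample_design_grid()
  expect_equal(nrow(grid), 200L)
  expect_equal(sort(unique(grid$gender)), c(0, 1))
  expect_length(unique(grid$age), 5L)
  expect_length(unique(grid$height), 5L)
  expect_length(unique(grid$bmi), 4L)
  # single-level axes collapse to midpoints
  single <- sample_design_grid(counts = c(age = 1L, height = 1L, bmi = 1L),
                               gender_levels = 0.5)
  expect_equal(nrow(single), 1L)
  expect_equal(single$age, 50)
  expect_equal(single$height, 1.7)
  # 2x2x2x2: all extreme combinations present
  g16 <- sample_design_grid(counts = c(age = 2L, height = 2L, bmi = 2L))
  expect_equal(nrow(g16), 16L)
  expect_equal(nrow(unique(g16)), 16L)
  expect_true(all(g16$age %in% c(10, 90)))
  expect_error(sample_design_grid(total = 199), "total")
})
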