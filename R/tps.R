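#' Solve a 3-D thin-plate-spline transform between landmark sets
#'
#' Fits the volumetric thin-plate-spline / biharmonic radial-basis
#' interpolant `f(x) = c + B x + sum_i w_i * phi(||x - s_i||)` with
#' `phi(r) = r` (the standard 3-D biharmonic kernel) mapping each source
#' landmark `s_i` to its target. The radial weights satisfy the usual side
#' conditions (`sum_i w_i = 0` and `sum_i w_i s_i' = 0`), which make the
#' transform reproduce affine maps exactly. With `lambda = 0` the map
#' interpolates the landmarks exactly; `lambda > 0` adds `lambda * I` to the
#' kernel block for a smoothed (approximating) fit.
#'
#' @param source m x 3 matrix of source landmarks (mm), m >= 4 non-coplanar.
#' @param target m x 3 matrix of target landmarks, row-aligned with `source`.
#' @param lambda regularization, >= 0 (default 0: exact interpolation).
#' @return An object of class `tps_transform` with `source_landmarks`,
#'   `radial_weights` (m x 3), `affine` (`list(B, c)`), `kernel`, `lambda`,
#'   `condition` (estimated condition number of the system).
#' @export
solve_tps <- function(source, target, lambda = 0) {
  source <- as.matrix(source); target <- as.matrix(target)
  storage.mode(source) <- storage.mode(target) <- "double"
  m <- nrow(source)
  if (m < 4L) stop("need at least 4 source landmarks")
  if (!all(dim(source) == dim(target)))
    stop("source and target must be row-aligned m x 3 matrices")
  if (lambda < 0) stop("lambda must be >= 0")
  dup <- duplicated(round(source, 12L))
  if (any(dup))
    stop("singular TPS system: duplicate source landmarks at rows ",
         paste(which(dup), collapse = ", "))
  ctr <- sweep(source, 2L, colMeans(source))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[3L] / sv[1L] < 1e-10)
    stop("singular TPS system: source landmarks are coplanar/collinear")
  # the kernel phi(r) = r is homogeneous, so the same transform family can
  # be solved in a centred, unit-scaled source frame (much better
  # conditioned) and mapped back exactly to raw coordinates
  mu <- colMeans(source)
  h <- sqrt(mean(rowSums(sweep(source, 2L, mu)^2)))
  if (h == 0) h <- 1
  u <- sweep(source, 2L, mu) / h
  k <- as.matrix(stats::dist(u))
  p <- cbind(1, u)                             # m x 4 polynomial block
  a <- rbind(cbind(k + diag(lambda / h, m), p),
             cbind(t(p), matrix(0, 4L, 4L)))
  rhs <- rbind(target, matrix(0, 4L, 3L))
  cond <- kappa(a, exact = FALSE)
  if (cond > 1e12)
    warning("TPS system is ill-conditioned (condition number ~ ",
            format(cond, digits = 3), ")")
  sol <- solve(a, rhs)
  w <- sol[seq_len(m), , drop = FALSE] / h     # ||u - u_i|| = ||x - s_i|| / h
  b <- t(sol[m + 2:4, , drop = FALSE]) / h
  dimnames(w) <- dimnames(b) <- NULL
  cvec <- as.numeric(sol[m + 1L, ]) - as.numeric(b %*% mu)
  structure(list(source_landmarks = source,
                 radial_weights = w,
                 affine = list(B = b, c = cvec),
                 kernel = "biharmonic-3d", lambda = lambda,
                 condition = cond),
            class = "tps_transform")
}

#' @export
print.tps_transform <- function(x, ...) {
  cat("<tps_transform> ", nrow(x$source_landmarks),
      " landmarks, kernel = ", x$kernel, ", lambda = ", x$lambda, "\n",
      sep = "")
  invisible(x)
}

#' Apply a thin-plate-spline transform to points
#'
#' Evaluates `f(x) = c + B x + sum_i w_i * ||x - s_i||` at each query point.
#'
#' @param transform a [solve_tps] result.
#' @param points p x 3 matrix.
#' @return p x 3 matrix of transformed points.
#' @export
apply_tps <- function(transform, points) {
  points <- as.matrix(points); storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("points must be p x 3")
  s <- transform$source_landmarks
  # p x m distance matrix, chunked to bound memory on large meshes
  p <- nrow(points)
  out <- matrix(0, p, 3L)
  chunk <- max(1L, as.integer(2e6 / nrow(s)))
  for (start in seq(1L, p, by = chunk)) {
    idx <- start:min(start + chunk - 1L, p)
    q <- points[idx, , drop = FALSE]
    # differences first: the expanded |q|^2 + |s|^2 - 2 q.s form loses
    # precision exactly where it matters most (points at landmarks)
    d <- matrix(0, nrow(q), nrow(s))
    for (i in seq_len(nrow(s)))
      d[, i] <- sqrt((q[, 1L] - s[i, 1L])^2 + (q[, 2L] - s[i, 2L])^2 +
                       (q[, 3L] - s[i, 3L])^2)
    out[idx, ] <- d %*% transform$radial_weights +
      q %*% t(transform$affine$B) +
      matrix(transform$affine$c, nrow(q), 3L, byrow = TRUE)
  }
  out
}

#' Morph a finite-element mesh onto target landmarks
#'
#' Solves the TPS transform from the mesh's own landmark nodes to the target
#' landmark positions and applies it to every node of the mesh — skull and
#' brain parts move under the one shared field, so interior tissue follows
#' the skull geometry. Connectivity, ids, parts and the landmark set are
#' untouched.
#'
#' @param baseline an [fe_mesh] whose `landmark_set` has one node per target
#'   row, in the same order.
#' @param target_landmarks m x 3 matrix.
#' @param lambda TPS regularization (default 0, exact landmark matching).
#' @return A morphed [fe_mesh].
#' @export
morph_mesh <- function(baseline, target_landmarks, lambda = 0) {
  target_landmarks <- as.matrix(target_landmarks)
  if (length(baseline$landmark_set) != nrow(target_landmarks))
    stop("landmark count mismatch: mesh has ", length(baseline$landmark_set),
         ", target has ", nrow(target_landmarks))
  src <- landmark_coords(baseline)
  tr <- solve_tps(src, target_landmarks, lambda = lambda)
  out <- baseline
  out$node_coords <- apply_tps(tr, baseline$node_coords)
  colnames(out$node_coords) <- c("x", "y", "z")
  out
}
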