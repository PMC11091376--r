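test_that("scaled Jacobian: unit cube is 1, sheared cube matches brute force", {
  cube <- unit_cube_corners()
  expect_equal(scaled_jacobian(cube, "solid"), 1.0, tolerance = 1e-12)
  # shear the top face in x
  sheared <- cube
  sheared[5:8, 1] <- sheared[5:8, 1] + 1
  # brute force: per-corner determinant over the 8 corner edge triads
  triads <- list(c(2, 4, 5), c(3, 1, 6), c(4, 2, 7), c(1, 3, 8),
                 c(8, 6, 1), c(5, 7, 2), c(6, 8, 3), c(7, 5, 4))
  brute <- min(vapply(1:8, function(i) {
    e <- sheared[triads[[i]], ] - matrix(sheared[i, ], 3, 3, byrow = TRUE)
    det(e) / prod(sqrt(rowSums(e^2)))
  }, numeric(1)))
  expect_equal(scaled_jacobian(sheared, "solid"), brute, tolerance = 1e-12)
  expect_lt(brute, 1)
})

test_that("degenerate elements flag instead of erroring", {
  cube <- unit_cube_corners()
  cube[2, ] <- cube[1, ]                  # coincident corners
  v <- scaled_jacobian(cube, "solid")
  expect_true(v <= 0)
  expect_true(isTRUE(attr(v, "degenerate")))
})

test_that("shell Jacobian and skew take their ideal values on ideal elements", {
  square <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(scaled_jacobian(square, "shell"), 1.0, tolerance = 1e-12)
  expect_equal(skew(square, "shell"), 0.0, tolerance = 1e-12)
  eq_tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  expect_equal(skew(eq_tri, "shell"), 0.0, tolerance = 1e-12)
})

test_that("parallelogram skew matches the closed-form value 1/3", {
  # angles 60/120 degrees: max((120-90)/90, (90-60)/90) = 1/3
  para <- rbind(c(0, 0, 0), c(1, 0, 0),
                c(1 + cos(pi / 3), sin(pi / 3), 0), c(cos(pi / 3), sin(pi / 3), 0))
  expect_equal(skew(para, "shell"), 1 / 3, tolerance = 1e-12)
})

test_that("tet metrics: regular tet has zero skew, unit corner tet known value", {
  # regular tet with positive (keyword-convention) orientation
  reg <- rbind(c(1, 1, 1), c(-1, 1, -1), c(1, -1, -1), c(-1, -1, 1))
  expect_equal(skew(reg, "solid"), 0, tolerance = 1e-12)
  expect_gt(scaled_jacobian(reg, "solid"), 0)
  # right-angle corner tet: corner 1 has orthonormal edges (value 1); each
  # other corner has edge lengths 1, sqrt(2), sqrt(2) with det 1, so the
  # minimum corner value is 1/2
  corner <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(scaled_jacobian(corner, "solid"), 0.5, tolerance = 1e-9)
})

test_that("quality metrics are invariant under rigid motion and uniform scale", {
  set.seed(61)
  cube <- unit_cube_corners() + matrix(stats::rnorm(24, sd = 0.1), 8, 3)
  quad <- rbind(c(0, 0, 0), c(1.2, 0.1, 0), c(1.3, 1.1, 0.2), c(-0.1, 0.9, 0.1))
  for (rep in 1:5) {
    r <- random_rotation(); t <- stats::rnorm(3, sd = 50); s <- stats::runif(1, 0.5, 2)
    cube2 <- s * cube %*% r + matrix(t, 8, 3, byrow = TRUE)
    quad2 <- s * quad %*% r + matrix(t, 4, 3, byrow = TRUE)
    expect_equal(scaled_jacobian(cube2, "solid"), scaled_jacobian(cube, "solid"),
                 tolerance = 1e-9)
    expect_equal(skew(cube2, "solid"), skew(cube, "solid"), tolerance = 1e-9)
    expect_equal(scaled_jacobian(quad2, "shell"), scaled_jacobian(quad, "shell"),
                 tolerance = 1e-9)
    expect_equal(skew(quad2, "shell"), skew(quad, "shell"), tolerance = 1e-9)
  }
})

test_that("identity, rigid and uniform-scale morphs give zero change rates", {
  bm <- generate_baseline_mesh(c(nlat = 5L, nlon = 10L, nbox = 3L),
                               n_landmarks = 20L)
  mesh <- bm$mesh
  expect_change_zero <- function(morphed) {
    rep <- quality_change_rate(mesh, morphed)
    expect_lt(max(rep$per_element$jacobian_change), 1e-8)
    expect_lt(max(rep$per_element$skew_change), 1e-8)
    expect_lt(max(rep$summary$max_change), 1e-8)
  }
  expect_change_zero(mesh)
  set.seed(62)
  r <- random_rotation()
  rigid <- mesh
  rigid$node_coords <- mesh$node_coords %*% r +
    matrix(c(30, -12, 5), nrow(mesh$node_coords), 3, byrow = TRUE)
  expect_change_zero(rigid)
  scaled <- mesh
  scaled$node_coords <- mesh$node_coords * 1.1
  expect_change_zero(scaled)
  other <- generate_baseline_mesh(c(nlat = 4L, nlon = 8L, nbox = 2L),
                                  n_landmarks = 10L)$mesh
  expect_error(quality_change_rate(mesh, other), "connectivity")
})

test_that("point-surface distance equals the exhaustive scan and closed forms", {
  set.seed(63)
  bm <- generate_baseline_mesh(c(nlat = 6L, nlon = 16L, nbox = 2L),
                               n_landmarks = 10L)
  surf <- bm$surface           # 192 triangles
  pts <- random_landmarks(50, scale = 70)
  fast <- point_surface_distance(pts, surf)
  slow <- point_surface_distance(pts, surf, exhaustive = TRUE)
  expect_equal(fast, slow, tolerance = 1e-12)
  # nodes on the surface itself are at distance zero
  on_surf <- surf$vertices[sample(nrow(surf$vertices), 20), ]
  expect_lt(max(point_surface_distance(on_surf, surf)), 1e-9)
  # single node above a large triangle interior: distance = height
  tri <- tri_surface(rbind(c(-10, -10, 0), c(10, -10, 0), c(0, 10, 0)),
                     rbind(1:3))
  expect_equal(point_surface_distance(rbind(c(0, 0, 2.5)), tri), 2.5,
               tolerance = 1e-12)
})

test_that("surface error report selects skull part nodes and summarises", {
  bm <- generate_baseline_mesh()
  ge <- surface_distance_error(bm$mesh, 1, bm$surface)
  expect_lt(ge$max_error, 1e-9)
  expect_lte(ge$mean_error, ge$max_error)
  expect_error(surface_distance_error(bm$mesh, 99, bm$surface), "empty")
})

test_that("morph gates fire at the study thresholds and are monotone", {
  bm <- generate_baseline_mesh(c(nlat = 5L, nlon = 10L, nbox = 3L),
                               n_landmarks = 20L)
  rep0 <- quality_change_rate(bm$mesh, bm$mesh)
  ge0 <- surface_distance_error(bm$mesh, 1, bm$surface)
  expect_true(validate_morph(rep0, ge0)$pass)

  fake <- rep0
  fake$summary$max_change <- 0.12
  v <- validate_morph(fake, ge0)
  expect_false(v$pass)
  expect_match(paste(v$failures, collapse = ";"), "max quality change")

  fake2 <- rep0
  fake2$summary$min_jacobian <- 0.19
  v2 <- validate_morph(fake2, ge0)
  expect_false(v2$pass)
  expect_match(paste(v2$failures, collapse = ";"), "Jacobian")

  fake3 <- rep0
  ge_bad <- ge0; ge_bad$mean_error <- 4.5; ge_bad$max_error <- 6
  v3 <- validate_morph(fake3, ge_bad)
  expect_false(v3$pass)
  expect_length(v3$failures, 2L)

  # relaxing any gate never flips pass -> fail
  gates <- default_morph_gates()
  relaxed <- gates
  relaxed$max_change <- 0.5; relaxed$mean_change <- 0.5
  relaxed$min_jacobian <- -1; relaxed$mean_error_mm <- 100
  relaxed$max_error_mm <- 100
  for (fk in list(fake, fake2, fake3)) {
    before <- validate_morph(fk, ge0, gates)$pass
    after <- validate_morph(fk, ge0, relaxed)$pass
    expect_true(after >= before)
  }
})
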