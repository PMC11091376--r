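# Synthetic study-condition generators.
#
# These generators stand in for data the study pipeline consumes but which
# cannot ship: a CT-derived landmark cohort, the baseline skull+brain FE
# mesh, cadaver signal pairs, and the crash-simulation injury table. Each
# is deterministic under a fixed seed and returns its own ground truth so
# the analysis modules can be tested against construction.

#' Population specification for the synthetic landmark cohort
#'
#' Cohort structure mirrors the study sample: n = 124 subjects, m = 69 skull
#' landmarks, gender ~ Bernoulli(0.5), age ~ U(10, 90) years, stature normal
#' with gender-conditional means 1.61 / 1.73 m (sd 0.09 m) — height is the
#' only characteristic correlated with gender — and BMI ~ U(15, 35) kg/m^2.
#' Landmark geometry is exactly linear in the centred characteristics
#' through a rank-`q` ground-truth coefficient map, plus isotropic Gaussian
#' landmark noise.
#'
#' @param n_subjects cohort size (default 124).
#' @param n_landmarks landmarks per subject (default 69).
#' @param q rank of the ground-truth characteristic effect (default 5).
#' @param noise_sigma landmark noise sd in mm (default 0.5).
#' @param template optional m x 3 matrix of template landmark positions;
#'   the default is a spherical-Fibonacci layout on a head-sized ellipsoid.
#'   Passing a baseline mesh's landmark coordinates here makes predicted
#'   subjects directly usable as morph targets for that mesh.
#' @param seed RNG seed.
#' @return list of class `population_spec`.
#' @export
population_spec <- function(n_subjects = 124L, n_landmarks = 69L, q = 5L,
                            noise_sigma = 0.5, template = NULL, seed = 1L) {
  if (!is.null(template)) {
    template <- as.matrix(template)
    if (ncol(template) != 3L) stop("template must be m x 3")
    n_landmarks <- nrow(template)
  }
  if (n_landmarks < 4L) stop("need at least 4 landmarks")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_landmarks = as.integer(n_landmarks), q = as.integer(q),
                 noise_sigma = noise_sigma, template = template,
                 seed = as.integer(seed)),
            class = "population_spec")
}

# template skull landmark layout: spherical-Fibonacci points on a head-sized
# ellipsoid (half-axes 75 x 95 x 85 mm: lateral, anterior-posterior,
# vertical), in mm
template_landmarks <- function(m) {
  i <- seq_len(m) - 0.5
  golden <- (1 + sqrt(5)) / 2
  phi <- acos(1 - 2 * i / m)
  theta <- 2 * pi * i / golden
  cbind(75 * sin(phi) * cos(theta),
        95 * sin(phi) * sin(theta),
        85 * cos(phi))
}

# centring constants and scales for the characteristic sampler; fixed so the
# ground-truth linear map is defined on a stable scale
char_centers <- c(gender = 0.5, age = 50, height = 1.67, bmi = 25)
char_scales <- c(gender = 0.5, age = 23, height = 0.09, bmi = 5.8)

#' Generate a synthetic landmark population with known ground truth
#'
#' Landmark configurations are `template + C z + noise`, where `z` is the
#' centred/scaled characteristic 4-vector and `C` the rank-q ground-truth
#' map. The leading effect direction is the radial (overall head size)
#' mode, loaded chiefly on height and BMI; the remaining directions are
#' seeded random orthonormal modes. With `noise_sigma = 0` the population is
#' exactly linear in the characteristics, so shape-model recovery of `C` is
#' exact up to numerical error.
#'
#' @param spec a [population_spec].
#' @return list with `subjects`, `characteristics` (n x 4 data.frame),
#'   `landmarks` (list of m x 3), `true_map` (3m x 4 linear map on the
#'   centred/scaled characteristic scale), `template` (m x 3),
#'   `char_centers`, `char_scales`.
#' @export
generate_population <- function(spec = population_spec()) {
  set.seed(spec$seed)
  n <- spec$n_subjects; m <- spec$n_landmarks; q <- spec$q
  gender <- stats::rbinom(n, 1L, 0.5)
  age <- stats::runif(n, 10, 90)
  height <- stats::rnorm(n, ifelse(gender == 0, 1.61, 1.73), 0.09)
  bmi <- stats::runif(n, 15, 35)
  chars <- data.frame(gender = gender, age = age, height = height, bmi = bmi)

  tmpl <- if (is.null(spec$template)) template_landmarks(m) else spec$template
  flat <- as.numeric(t(tmpl))
  d1 <- flat / sqrt(sum(flat^2))          # radial size mode
  # remaining modes are random but spatially smooth vector fields over the
  # template (random coefficients on low-order monomials of position), as
  # anatomical variation is — spatially white modes would make morphed
  # meshes unrealistically rough near landmarks
  u <- sweep(tmpl, 2L, apply(abs(tmpl), 2L, max), "/")
  basis_fun <- cbind(1, u, u[, 1L] * u[, 2L], u[, 1L] * u[, 3L],
                     u[, 2L] * u[, 3L], u^2)
  dirs <- vapply(seq_len(q - 1L), function(j) {
    coef <- matrix(stats::rnorm(ncol(basis_fun) * 3L), ncol(basis_fun), 3L)
    as.numeric(t(basis_fun %*% coef))
  }, numeric(3L * m))
  dirs <- cbind(d1, dirs)
  dirs <- qr.Q(qr(dirs))[, seq_len(q), drop = FALSE]
  # mode loadings (mm of displacement per 1-sd characteristic deviation):
  # size driven by height and BMI, weaker age/gender effects on the rest
  loadings <- matrix(0, q, 4L)
  loadings[1L, ] <- c(1.0, 0.3, 4.0, 2.0)
  extra <- matrix(stats::rnorm(4L * (q - 1L), sd = 1.0), q - 1L, 4L)
  if (q > 1L) loadings[2:q, ] <- extra
  true_map <- dirs %*% loadings            # 3m x 4

  z <- sweep(sweep(as.matrix(chars), 2L, char_centers), 2L, char_scales, "/")
  lms <- vector("list", n)
  for (i in seq_len(n)) {
    x <- flat + as.numeric(true_map %*% z[i, ])
    if (spec$noise_sigma > 0)
      x <- x + stats::rnorm(3L * m, sd = spec$noise_sigma)
    lms[[i]] <- matrix(x, ncol = 3L, byrow = TRUE)
  }
  list(subjects = sprintf("S%03d", seq_len(n)), characteristics = chars,
       landmarks = lms, true_map = true_map, template = tmpl,
       char_centers = char_centers, char_scales = char_scales)
}

#' Generate a synthetic baseline skull+brain FE mesh
#'
#' Builds a two-part head-scale mesh: an "skull" of quadrilateral shell
#' elements on an ellipsoid (half-axes 75 x 95 x 85 mm, latitude bands away
#' from the poles so all quads stay well-shaped) and a "brain" of perfect
#' hexahedral lattice cells inscribed in the ellipsoid. 69 landmark nodes
#' (configurable) are spread deterministically over the shell, and a
#' companion triangulated surface shares the shell vertices, so landmark
#' nodes lie exactly on it.
#'
#' @param resolution list or vector with `nlat` (latitude bands, >= 4),
#'   `nlon` (longitude steps, >= 8) and `nbox` (brain lattice cells per
#'   axis, >= 2); default `c(nlat = 8, nlon = 16, nbox = 4)`.
#' @param n_landmarks landmark count (default 69; capped at the shell node
#'   count).
#' @return list with `mesh` (an [fe_mesh]) and `surface` (the companion
#'   [tri_surface]).
#' @export
generate_baseline_mesh <- function(resolution = c(nlat = 8L, nlon = 16L,
                                                  nbox = 4L),
                                   n_landmarks = 69L) {
  nlat <- max(4L, as.integer(resolution[["nlat"]]))
  nlon <- max(8L, as.integer(resolution[["nlon"]]))
  nbox <- max(2L, as.integer(resolution[["nbox"]]))
  ax <- c(75, 95, 85)
  lat <- seq(-75, 75, length.out = nlat + 1L) * pi / 180
  lon <- seq(0, 2 * pi, length.out = nlon + 1L)[-(nlon + 1L)]
  # a latitude-dependent twist keeps nodes on the ellipsoid but gives the
  # quads moderate baseline skew, as real surface meshes have; perfectly
  # rectangular patches would make relative skew-change rates meaningless
  shell_xyz <- do.call(rbind, lapply(lat, function(la) {
    lo <- lon + 0.4 * la
    cbind(ax[1L] * cos(la) * cos(lo), ax[2L] * cos(la) * sin(lo),
          ax[3L] * sin(la))
  }))
  n_shell <- nrow(shell_xyz)
  ring <- function(i, j) (i - 1L) * nlon + ((j - 1L) %% nlon) + 1L
  quads <- do.call(rbind, lapply(seq_len(nlat), function(i)
    t(vapply(seq_len(nlon), function(j)
      c(ring(i, j), ring(i, j + 1L), ring(i + 1L, j + 1L), ring(i + 1L, j)),
      integer(4L)))))
  shells <- data.frame(id = seq_len(nrow(quads)), part = 1L,
                       n1 = quads[, 1L], n2 = quads[, 2L],
                       n3 = quads[, 3L], n4 = quads[, 4L])

  half <- ax / sqrt(3) * 0.8               # inscribed brain box half-sizes
  g <- lapply(half, function(h) seq(-h, h, length.out = nbox + 1L))
  brain_xyz <- as.matrix(expand.grid(x = g[[1L]], y = g[[2L]], z = g[[3L]]))
  # shear the lattice: a perfect box lattice has exactly zero skew, which no
  # real brain mesh does and which makes relative quality-change rates
  # meaningless; moderate baseline skew keeps them well-behaved
  shear <- rbind(c(1, 0.22, 0.15), c(0, 1, 0.18), c(0, 0, 1))
  brain_xyz <- brain_xyz %*% t(shear)
  bid <- function(i, j, k) n_shell +
    (k - 1L) * (nbox + 1L) * (nbox + 1L) + (j - 1L) * (nbox + 1L) + i
  hexas <- do.call(rbind, lapply(seq_len(nbox), function(k)
    do.call(rbind, lapply(seq_len(nbox), function(j)
      t(vapply(seq_len(nbox), function(i)
        c(bid(i, j, k), bid(i + 1L, j, k), bid(i + 1L, j + 1L, k),
          bid(i, j + 1L, k), bid(i, j, k + 1L), bid(i + 1L, j, k + 1L),
          bid(i + 1L, j + 1L, k + 1L), bid(i, j + 1L, k + 1L)),
        integer(8L)))))))
  solids <- data.frame(id = nrow(shells) + seq_len(nrow(hexas)), part = 2L,
                       n1 = hexas[, 1L], n2 = hexas[, 2L], n3 = hexas[, 3L],
                       n4 = hexas[, 4L], n5 = hexas[, 5L], n6 = hexas[, 6L],
                       n7 = hexas[, 7L], n8 = hexas[, 8L])

  n_landmarks <- min(as.integer(n_landmarks), n_shell)
  lmk <- unique(round(seq(1L, n_shell, length.out = n_landmarks)))
  while (length(lmk) < n_landmarks)
    lmk <- sort(unique(c(lmk, sample.int(n_shell, 1L))))
  mesh <- fe_mesh(node_ids = seq_len(n_shell + nrow(brain_xyz)),
                  node_coords = rbind(shell_xyz, brain_xyz),
                  shells = shells, solids = solids,
                  landmark_set = as.integer(lmk),
                  part_labels = c(`1` = "skull", `2` = "brain"))
  tris <- rbind(quads[, c(1L, 2L, 3L)], quads[, c(1L, 3L, 4L)])
  surface <- tri_surface(shell_xyz, tris)
  list(mesh = mesh, surface = surface)
}

#' Injury generator specification
#'
#' Defines the latent crash-response model and the record design of the
#' synthetic injury dataset. The latent response rises linearly with impact
#' speed and age, falls with BMI, is higher for pedestrians than cyclists,
#' varies non-monotonically with stature (piecewise around 1.70 m, mirroring
#' the erratic height effect), and carries Gaussian noise; realized values
#' are affinely rescaled so the dataset spans exactly
#' `[span_kpa[1], span_kpa[2]]` kPa.
#'
#' The default record design is a near-factorial layout over impact speeds
#' on a 5 km/h grid (20-60 km/h, 9 levels) crossed with both traffic states
#' (18 cells); 12 cells carry 101 records and 6 carry 100, totalling 1812.
#' Within each cell, age and BMI take evenly spaced grid values (randomly
#' paired) and gender alternates, so characteristic margins are balanced
#' across speed and state.
#'
#' @param beta_speed,beta_age,beta_bmi,beta_height,beta_state latent effect
#'   sizes (per km/h above 20, per year above 10, per kg/m^2 below 25, per
#'   metre of |height - 1.70|, and the pedestrian offset); all positive.
#' @param noise_sigma latent noise sd.
#' @param speeds impact-speed levels (km/h).
#' @param total total record count (default 1812).
#' @param span_kpa calibration span of the rescaled response (kPa).
#' @param seed RNG seed.
#' @return list of class `injury_generator_spec`.
#' @export
injury_generator_spec <- function(beta_speed = 1.0, beta_age = 0.062,
                                  beta_bmi = 0.235, beta_height = 1.0,
                                  beta_state = 1.0, noise_sigma = 0.25,
                                  speeds = seq(20, 60, by = 5),
                                  total = 1812L,
                                  span_kpa = c(4.4, 46.9), seed = 1L) {
  if (any(c(beta_speed, beta_age, beta_bmi, beta_state) <= 0))
    stop("speed, age, BMI and state effects must be positive")
  structure(list(beta_speed = beta_speed, beta_age = beta_age,
                 beta_bmi = beta_bmi, beta_height = beta_height,
                 beta_state = beta_state, noise_sigma = noise_sigma,
                 speeds = speeds, total = as.integer(total),
                 span_kpa = span_kpa, seed = as.integer(seed)),
            class = "injury_generator_spec")
}

#' Generate the calibrated synthetic injury dataset
#'
#' Realizes the design in [injury_generator_spec]: balanced characteristic
#' grids within each speed-by-state cell, the latent response model, and
#' min-max affine rescaling of the response onto the calibration span (so
#' the dataset minimum and maximum hit the span endpoints by construction).
#' Injury classes are then assigned with [classify_injury].
#'
#' @param spec an [injury_generator_spec].
#' @return An [injury_dataset] whose `design_meta` attribute records the
#'   cell layout and seed.
#' @export
generate_injury_dataset <- function(spec = injury_generator_spec()) {
  set.seed(spec$seed)
  cells <- expand.grid(speed = spec$speeds, state = c(0, 1))
  ncell <- nrow(cells)
  base <- spec$total %/% ncell
  extra <- spec$total %% ncell
  sizes <- rep(base, ncell) + c(rep(1L, extra), rep(0L, ncell - extra))
  recs <- vector("list", ncell)
  for (ci in seq_len(ncell)) {
    nc <- sizes[ci]
    age <- sample(10 + (seq_len(nc) - 0.5) * 80 / nc)
    bmi <- sample(15 + (seq_len(nc) - 0.5) * 20 / nc)
    gender <- sample(rep_len(c(0, 1), nc))
    height <- stats::rnorm(nc, ifelse(gender == 0, 1.61, 1.73), 0.09)
    recs[[ci]] <- data.frame(gender = gender, age = age, height = height,
                             bmi = bmi, state = cells$state[ci],
                             speed_kmh = cells$speed[ci])
  }
  df <- do.call(rbind, recs)
  latent <- spec$beta_speed * (df$speed_kmh - 20) +
    spec$beta_age * (df$age - 10) -
    spec$beta_bmi * (df$bmi - 25) -
    spec$beta_height * abs(df$height - 1.70) +
    spec$beta_state * (1 - df$state) +
    stats::rnorm(nrow(df), sd = spec$noise_sigma)
  rng <- range(latent)
  if (diff(rng) == 0)
    stop("infeasible calibration: latent response is constant")
  df$von_mises_kpa <- spec$span_kpa[1L] +
    (latent - rng[1L]) * diff(spec$span_kpa) / diff(rng)
  injury_dataset(df, design_meta = list(cells = cells, sizes = sizes,
                                        seed = spec$seed))
}

#' Generate an analytically related pair of test signals
#'
#' Deterministic signal pairs with a known relationship, used to exercise
#' the biofidelity rating: `identical` (equal half-sine pulses), `scaled`
#' (test = factor * ref), `shifted` (periodic sine with the test delayed by
#' a set fraction of the allowed phase window) and `noisy` (seeded additive
#' Gaussian noise).
#'
#' @param kind one of `"identical"`, `"scaled"`, `"shifted"`, `"noisy"`.
#' @param params list: `factor` (scaled, default 2), `shift_frac` (shifted:
#'   fraction of the maximum phase window `d_max * T`, default 0.5),
#'   `d_max` (default 0.12), `noise_sd` (noisy, default 0.05), `n` samples
#'   (default 1001), `duration` s (default 1).
#' @param seed RNG seed (used by `"noisy"` only).
#' @return list with `ref` and `test` [hm_signal]s and the realized `params`.
#' @export
generate_signal_pair <- function(kind = c("identical", "scaled", "shifted",
                                          "noisy"),
                                 params = list(), seed = 1L) {
  kind <- match.arg(kind)
  p <- utils::modifyList(list(factor = 2, shift_frac = 0.5, d_max = 0.12,
                              noise_sd = 0.05, n = 1001L, duration = 1),
                         params)
  t <- seq(0, p$duration, length.out = p$n)
  if (kind == "shifted") {
    # periodic fixture: period = duration / 2 keeps the optimum unique
    # within the phase search window
    delay <- p$shift_frac * p$d_max * p$duration
    ref <- sin(2 * pi * 2 * t / p$duration)
    test <- sin(2 * pi * 2 * (t - delay) / p$duration)
    p$delay <- delay
  } else {
    ref <- sin(pi * t / p$duration)        # half-sine pulse
    test <- switch(kind,
                   identical = ref,
                   scaled = p$factor * ref,
                   noisy = { set.seed(seed)
                     ref + stats::rnorm(p$n, sd = p$noise_sd) })
  }
  list(ref = hm_signal(t, ref), test = hm_signal(t, test), params = p)
}
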