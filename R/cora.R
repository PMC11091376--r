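#' CORA rating configuration
#'
#' Settings for the corridor-plus-cross-correlation biofidelity rating.
#' Corridor half-widths are constant fractions of the reference peak
#' (`a0` inner, `b0` outer); `d_max` bounds the phase-shift search as a
#' fraction of the evaluation window; the weight sets combine the corridor
#' score with the cross-correlation block (shape/size/phase) into a single
#' total in `[0, 1]`.
#'
#' @param a0 inner corridor fraction of the reference peak (default 0.05).
#' @param b0 outer corridor fraction (default 0.5); must exceed `a0`.
#' @param d_max maximum phase shift as a fraction of the window (default 0.12).
#' @param w_corridor,w_cross top-level weights (default 0.5 / 0.5).
#' @param w_shape,w_size,w_phase weights within the cross-correlation block
#'   (default 0.5 / 0.25 / 0.25).
#' @param n_resample number of uniform samples for the common grid
#'   (default 1000).
#' @return list of class `cora_config`.
#' @export
cora_config <- function(a0 = 0.05, b0 = 0.5, d_max = 0.12,
                        w_corridor = 0.5, w_cross = 0.5,
                        w_shape = 0.5, w_size = 0.25, w_phase = 0.25,
                        n_resample = 1000L) {
  if (!(a0 > 0 && a0 < b0)) stop("corridor fractions must satisfy 0 < a0 < b0")
  if (abs(w_corridor + w_cross - 1) > 1e-12)
    stop("top-level weights must sum to 1")
  if (abs(w_shape + w_size + w_phase - 1) > 1e-12)
    stop("cross-correlation weights must sum to 1")
  structure(list(a0 = a0, b0 = b0, d_max = d_max,
                 w_corridor = w_corridor, w_cross = w_cross,
                 w_shape = w_shape, w_size = w_size, w_phase = w_phase,
                 n_resample = as.integer(n_resample)),
            class = "cora_config")
}

#' Resample two signals onto a common uniform grid
#'
#' Linear interpolation of both signals onto `n` uniform points over the
#' overlap of their time supports.
#'
#' @param ref,test [hm_signal] objects with overlapping time support.
#' @param n number of uniform samples.
#' @return list with `times` (length n), `ref`, `test` (interpolated values).
#' @export
resample_common_grid <- function(ref, test, n = 1000L) {
  lo <- max(ref$times[1L], test$times[1L])
  hi <- min(ref$times[length(ref$times)], test$times[length(test$times)])
  if (hi <= lo) stop("signals have no overlapping time support")
  grid <- seq(lo, hi, length.out = n)
  list(times = grid,
       ref = stats::approx(ref$times, ref$values, xout = grid)$y,
       test = stats::approx(test$times, test$values, xout = grid)$y)
}

#' Corridor sub-rating
#'
#' Per-sample score: 1 inside the inner corridor (`|test - ref|` at most
#' `a0 * max|ref|`), 0 outside the outer corridor (`b0 * max|ref|`), linear
#' in between; the rating is the mean over samples.
#'
#' @param ref,test numeric vectors on a shared uniform grid.
#' @param a0,b0 corridor fractions of the reference peak.
#' @return corridor rating in `[0, 1]`.
#' @export
corridor_rating <- function(ref, test, a0 = 0.05, b0 = 0.5) {
  peak <- max(abs(ref))
  if (peak == 0) stop("corridor undefined for an all-zero reference")
  inner <- a0 * peak; outer <- b0 * peak
  delta <- abs(test - ref)
  score <- ifelse(delta <= inner, 1,
                  ifelse(delta >= outer, 0,
                         (outer - delta) / (outer - inner)))
  mean(score)
}

#' Cross-correlation sub-ratings: shape, size, phase
#'
#' Searches integer sample shifts within `[-d_max * T, d_max * T]` (T the
#' window length) for the shift maximising the Pearson correlation between
#' the reference and the shifted test signal (ties broken toward the
#' smallest absolute shift). Shape is the positive part of that maximal
#' correlation; size is the ratio min/max of the squared-signal integrals of
#' the reference and the optimally shifted test over their overlap; phase is
#' `1 - |shift| / (d_max * T)`.
#'
#' @param ref,test numeric vectors on a shared uniform grid.
#' @param times the shared uniform time grid.
#' @param d_max maximum shift as a fraction of the window.
#' @return list with `shape`, `size`, `phase` in `[0, 1]`, the optimal
#'   `shift` (s) and `degenerate` flag (zero-variance input).
#' @export
cross_correlation_rating <- function(ref, test, times, d_max = 0.12) {
  n <- length(ref)
  dt <- times[2L] - times[1L]
  T <- times[n] - times[1L]
  max_lag <- floor(d_max * T / dt + 1e-9)
  if (stats::sd(ref) == 0 || stats::sd(test) == 0)
    return(list(shape = 0, size = 0, phase = 0, shift = 0, degenerate = TRUE))
  lags <- -max_lag:max_lag
  rho <- vapply(lags, function(l) {
    # positive lag delays test: compare ref[i] with test[i - l]
    ri <- if (l >= 0) (1L + l):n else 1L:(n + l)
    ti <- ri - l
    if (stats::sd(ref[ri]) == 0 || stats::sd(test[ti]) == 0) return(-Inf)
    stats::cor(ref[ri], test[ti])
  }, numeric(1L))
  best <- which(rho == max(rho))
  best <- best[which.min(abs(lags[best]))]
  l <- lags[best]
  ri <- if (l >= 0) (1L + l):n else 1L:(n + l)
  ti <- ri - l
  i_ref <- sum(ref[ri]^2) * dt
  i_test <- sum(test[ti]^2) * dt
  size <- if (max(i_ref, i_test) == 0) 0 else
    min(i_ref, i_test) / max(i_ref, i_test)
  phase <- if (max_lag == 0) 1 else
    min(max(1 - abs(l * dt) / (d_max * T), 0), 1)
  list(shape = max(0, rho[best]), size = size, phase = phase,
       shift = l * dt, degenerate = FALSE)
}

#' Combined CORA score for a signal pair
#'
#' Resamples the pair onto a common uniform grid, computes the corridor and
#' cross-correlation (shape/size/phase) sub-ratings and combines them with
#' the configured weights:
#' `total = w_corridor * corridor + w_cross * (w_shape * shape +
#' w_size * size + w_phase * phase)`.
#'
#' @param ref reference (experimental) [hm_signal].
#' @param test comparison (simulation) [hm_signal].
#' @param config a [cora_config].
#' @return object of class `cora_score` with fields `corridor`, `shape`,
#'   `size`, `phase`, `total`.
#' @export
cora_score <- function(ref, test, config = cora_config()) {
  rs <- resample_common_grid(ref, test, n = config$n_resample)
  corr <- corridor_rating(rs$ref, rs$test, a0 = config$a0, b0 = config$b0)
  cc <- cross_correlation_rating(rs$ref, rs$test, rs$times,
                                 d_max = config$d_max)
  total <- config$w_corridor * corr +
    config$w_cross * (config$w_shape * cc$shape + config$w_size * cc$size +
                        config$w_phase * cc$phase)
  structure(list(corridor = corr, shape = cc$shape, size = cc$size,
                 phase = cc$phase, total = total, shift = cc$shift,
                 degenerate = cc$degenerate),
            class = "cora_score")
}

#' @export
print.cora_score <- function(x, ...) {
  cat(sprintf(
    "<cora_score> total %.3f (corridor %.3f, shape %.3f, size %.3f, phase %.3f)\n",
    x$total, x$corridor, x$shape, x$size, x$phase))
  invisible(x)
}
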