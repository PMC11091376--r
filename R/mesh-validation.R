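# Element quality metrics.
#
# "Jacobian" here is the corner scaled Jacobian: for solids, the minimum over
# corners of det[e1,e2,e3]/(|e1||e2||e3|) of the corner's edge triad; for
# shells, the minimum over corners of the normalized 2-D cross product of the
# corner's two edges, signed by alignment with the element normal. "Skew" is
# the equiangular skew: max over interior angles theta of
# max((theta - te)/(180 - te), (te - theta)/te), te = 90 deg for quad faces
# and 60 deg for triangular faces; solids take the max over their faces.
# Both are invariant under rigid motion and uniform scaling.

# corner triads: for each corner, indices of the three adjacent corners in an
# order giving det = +1 on the reference element
hexa_corner_triads <- list(
  c(2L, 4L, 5L), c(3L, 1L, 6L), c(4L, 2L, 7L), c(1L, 3L, 8L),
  c(8L, 6L, 1L), c(5L, 7L, 2L), c(6L, 8L, 3L), c(7L, 5L, 4L))
tet_corner_triads <- list(
  c(2L, 3L, 4L), c(1L, 4L, 3L), c(1L, 2L, 4L), c(1L, 3L, 2L))

#' Corner scaled Jacobian of a single element
#'
#' @param coords corner coordinate matrix: 3 or 4 rows for shells, 4 (tet)
#'   or 8 (hexa) rows for solids; corners in keyword-file order.
#' @param element_class `"shell"` or `"solid"`.
#' @return the minimum corner value in `[-1, 1]`; a zero-length edge yields
#'   `-1` with attribute `degenerate = TRUE` rather than an error.
#' @export
scaled_jacobian <- function(coords, element_class = c("shell", "solid")) {
  element_class <- match.arg(element_class)
  coords <- as.matrix(coords)
  nc <- nrow(coords)
  if (element_class == "solid") {
    triads <- switch(as.character(nc), "4" = tet_corner_triads,
                     "8" = hexa_corner_triads,
                     stop("solid elements have 4 or 8 corners"))
    vals <- vapply(seq_len(nc), function(i) {
      e <- coords[triads[[i]], , drop = FALSE] -
        matrix(coords[i, ], 3L, 3L, byrow = TRUE)
      len <- sqrt(rowSums(e^2))
      if (any(len == 0)) return(NA_real_)
      det(e) / prod(len)
    }, numeric(1L))
  } else {
    if (!nc %in% c(3L, 4L)) stop("shell elements have 3 or 4 corners")
    # element normal from averaged corner cross products
    nxt <- c(seq_len(nc)[-1L], 1L); prv <- c(nc, seq_len(nc)[-nc])
    en <- cross3(coords[nxt, , drop = FALSE] - coords,
                 coords[prv, , drop = FALSE] - coords)
    normal <- colSums(en)
    nlen <- sqrt(sum(normal^2))
    if (nlen == 0) {
      out <- -1; attr(out, "degenerate") <- TRUE; return(out)
    }
    normal <- normal / nlen
    vals <- vapply(seq_len(nc), function(i) {
      e1 <- coords[nxt[i], ] - coords[i, ]
      e2 <- coords[prv[i], ] - coords[i, ]
      l1 <- sqrt(sum(e1^2)); l2 <- sqrt(sum(e2^2))
      if (l1 == 0 || l2 == 0) return(NA_real_)
      sum(cross3(rbind(e1), rbind(e2)) * normal) / (l1 * l2)
    }, numeric(1L))
  }
  if (anyNA(vals)) {
    out <- -1; attr(out, "degenerate") <- TRUE; return(out)
  }
  min(vals)
}

# faces of solid elements as corner-index rings (outward order not required
# for skew, which only uses interior angles)
hexa_faces <- list(c(1L, 2L, 3L, 4L), c(5L, 6L, 7L, 8L), c(1L, 2L, 6L, 5L),
                   c(2L, 3L, 7L, 6L), c(3L, 4L, 8L, 7L), c(4L, 1L, 5L, 8L))
tet_faces <- list(c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 3L, 4L), c(2L, 3L, 4L))

face_skew <- function(coords) {
  nc <- nrow(coords)
  te <- if (nc == 4L) 90 else 60
  nxt <- c(seq_len(nc)[-1L], 1L); prv <- c(nc, seq_len(nc)[-nc])
  worst <- 0
  for (i in seq_len(nc)) {
    e1 <- coords[nxt[i], ] - coords[i, ]
    e2 <- coords[prv[i], ] - coords[i, ]
    l1 <- sqrt(sum(e1^2)); l2 <- sqrt(sum(e2^2))
    if (l1 == 0 || l2 == 0) return(1)
    cs <- sum(e1 * e2) / (l1 * l2)
    if (abs(cs) >= 1 - 1e-14) return(1)   # collinear edges: degenerate angle
    theta <- acos(pmin(pmax(cs, -1), 1)) * 180 / pi
    worst <- max(worst, (theta - te) / (180 - te), (te - theta) / te)
  }
  min(worst, 1)
}

#' Equiangular skew of a single element
#'
#' @inheritParams scaled_jacobian
#' @return skew in `[0, 1]`: 0 for ideal interior angles (90 deg quad faces,
#'   60 deg triangular faces), 1 for a degenerate angle.
#' @export
skew <- function(coords, element_class = c("shell", "solid")) {
  element_class <- match.arg(element_class)
  coords <- as.matrix(coords)
  nc <- nrow(coords)
  if (element_class == "shell") {
    if (!nc %in% c(3L, 4L)) stop("shell elements have 3 or 4 corners")
    return(face_skew(coords))
  }
  faces <- switch(as.character(nc), "4" = tet_faces, "8" = hexa_faces,
                  stop("solid elements have 4 or 8 corners"))
  max(vapply(faces, function(f) face_skew(coords[f, , drop = FALSE]),
             numeric(1L)))
}

element_corner_list <- function(mesh, table, ncols) {
  lapply(seq_len(nrow(table)), function(i) {
    ids <- unlist(table[i, paste0("n", seq_len(ncols))], use.names = FALSE)
    ids <- ids[!is.na(ids)]
    mesh$node_coords[node_index(mesh, ids), , drop = FALSE]
  })
}

#' Per-element quality metrics of a mesh
#'
#' @param mesh an [fe_mesh].
#' @return data.frame with columns `id`, `class` ("shell"/"solid"),
#'   `jacobian`, `skew`.
#' @export
mesh_quality <- function(mesh) {
  rows <- list()
  if (!is.null(mesh$shells) && nrow(mesh$shells)) {
    cl <- element_corner_list(mesh, mesh$shells, 4L)
    rows[[1L]] <- data.frame(
      id = mesh$shells$id, class = "shell",
      jacobian = vapply(cl, function(c) as.numeric(scaled_jacobian(c, "shell")),
                        numeric(1L)),
      skew = vapply(cl, skew, numeric(1L), element_class = "shell"))
  }
  if (!is.null(mesh$solids) && nrow(mesh$solids)) {
    cl <- element_corner_list(mesh, mesh$solids, 8L)
    rows[[length(rows) + 1L]] <- data.frame(
      id = mesh$solids$id, class = "solid",
      jacobian = vapply(cl, function(c) as.numeric(scaled_jacobian(c, "solid")),
                        numeric(1L)),
      skew = vapply(cl, skew, numeric(1L), element_class = "solid"))
  }
  if (!length(rows)) stop("mesh has no elements")
  do.call(rbind, rows)
}

#' Mesh-quality change rates of a morphed mesh against its baseline
#'
#' For every element the relative change of each quality metric is
#' `|q_morphed - q_baseline| / max(|q_baseline|, floor)`; the floor guards
#' near-degenerate baseline elements. Summaries (mean and max change, and
#' the morphed minima) are split by element dimension class (2-D shells /
#' 3-D solids).
#'
#' @param baseline,morphed [fe_mesh] objects with identical element ids and
#'   connectivity.
#' @param floor change-rate denominator floor (default 1e-3).
#' @return An object of class `quality_report`: `per_element` data.frame
#'   (id, class, metric columns for both meshes and both change rates) and
#'   `summary` data.frame per dimension class.
#' @export
quality_change_rate <- function(baseline, morphed, floor = 1e-3) {
  same <- function(a, b) (is.null(a) && is.null(b)) ||
    (!is.null(a) && !is.null(b) && nrow(a) == nrow(b) &&
       isTRUE(all.equal(a[order(a$id), ], b[order(b$id), ],
                        check.attributes = FALSE)))
  if (!same(baseline$shells, morphed$shells) ||
      !same(baseline$solids, morphed$solids))
    stop("baseline and morphed meshes must share connectivity and element ids")
  qb <- mesh_quality(baseline)
  qm <- mesh_quality(morphed)
  qm <- qm[match(paste(qb$class, qb$id), paste(qm$class, qm$id)), ]
  per <- data.frame(
    id = qb$id, class = qb$class,
    jacobian_base = qb$jacobian, jacobian_morph = qm$jacobian,
    skew_base = qb$skew, skew_morph = qm$skew,
    jacobian_change = abs(qm$jacobian - qb$jacobian) /
      pmax(abs(qb$jacobian), floor),
    skew_change = abs(qm$skew - qb$skew) / pmax(abs(qb$skew), floor))
  summ <- do.call(rbind, lapply(split(per, per$class), function(d)
    data.frame(class = d$class[1L],
               min_jacobian = min(d$jacobian_morph),
               mean_change = mean(c(d$jacobian_change, d$skew_change)),
               max_change = max(c(d$jacobian_change, d$skew_change)))))
  rownames(summ) <- NULL
  structure(list(per_element = per, summary = summ, floor = floor),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# exact minimum distance from one point to one triangle (Eberly-style
# clamped projection onto the triangle's parameter domain)
point_triangle_distance <- function(p, a, b, c) {
  e0 <- b - a; e1 <- c - a; d <- a - p
  a00 <- sum(e0 * e0); a01 <- sum(e0 * e1); a11 <- sum(e1 * e1)
  b0 <- sum(e0 * d); b1 <- sum(e1 * d)
  det <- a00 * a11 - a01 * a01
  s <- a01 * b1 - a11 * b0
  t <- a01 * b0 - a00 * b1
  if (det <= .Machine$double.eps * max(a00, a11, 1)) {
    # degenerate triangle: fall back to nearest edge/vertex
    seg <- function(p0, p1) {
      v <- p1 - p0; tt <- sum((p - p0) * v) / max(sum(v * v), 1e-300)
      q <- p0 + min(max(tt, 0), 1) * v
      sum((p - q)^2)
    }
    return(sqrt(min(seg(a, b), seg(a, c), seg(b, c))))
  }
  if (s + t <= det) {
    if (s < 0) {
      if (t < 0) { s <- min(max(-b0 / a00, 0), 1); t <- 0
        if (b1 > -a01 * s) { t <- min(max(-b1 / a11, 0), 1); s <- 0 } }
      else { s <- 0; t <- min(max(-b1 / a11, 0), 1) }
    } else if (t < 0) { t <- 0; s <- min(max(-b0 / a00, 0), 1) }
    else { s <- s / det; t <- t / det }
  } else {
    if (s < 0) {
      tmp0 <- a01 + b0; tmp1 <- a11 + b1
      if (tmp1 > tmp0) { num <- tmp1 - tmp0
        s <- min(max(num / (a00 - 2 * a01 + a11), 0), 1); t <- 1 - s }
      else { s <- 0; t <- min(max(-b1 / a11, 0), 1) }
    } else if (t < 0) {
      tmp0 <- a01 + b1; tmp1 <- a00 + b0
      if (tmp1 > tmp0) { num <- tmp1 - tmp0
        t <- min(max(num / (a00 - 2 * a01 + a11), 0), 1); s <- 1 - t }
      else { t <- 0; s <- min(max(-b0 / a00, 0), 1) }
    } else { num <- (a11 + b1) - (a01 + b0)
      s <- min(max(num / (a00 - 2 * a01 + a11), 0), 1); t <- 1 - s }
  }
  q <- a + s * e0 + t * e1
  sqrt(sum((p - q)^2))
}

#' Minimum distances from points to a triangulated surface
#'
#' Exact point-to-triangle minimum distance over all target triangles for
#' each query point. A per-point lower-bound prune (distance to triangle
#' centroid minus circumscribing radius) skips triangles that cannot beat
#' the current best; the result is identical to the exhaustive scan.
#'
#' @param points p x 3 matrix.
#' @param target a [tri_surface].
#' @param exhaustive disable pruning (used by the oracle tests).
#' @return numeric vector of p distances (mm).
#' @export
point_surface_distance <- function(points, target, exhaustive = FALSE) {
  points <- as.matrix(points)
  v <- target$vertices; tr <- target$triangles
  if (!nrow(tr)) stop("target surface has no triangles")
  a <- v[tr[, 1L], , drop = FALSE]; b <- v[tr[, 2L], , drop = FALSE]
  cc <- v[tr[, 3L], , drop = FALSE]
  cen <- (a + b + cc) / 3
  rad <- sqrt(pmax(rowSums((a - cen)^2),
                   rowSums((b - cen)^2), rowSums((cc - cen)^2)))
  vapply(seq_len(nrow(points)), function(i) {
    p <- points[i, ]
    dcen <- sqrt(rowSums(sweep(cen, 2L, p)^2))
    ord <- order(dcen)
    best <- Inf
    for (j in ord) {
      if (!exhaustive && dcen[j] - rad[j] >= best) break
      d <- point_triangle_distance(p, a[j, ], b[j, ], cc[j, ])
      if (d < best) best <- d
    }
    best
  }, numeric(1L))
}

#' Geometric error of a morphed mesh against a target surface
#'
#' Distance from each node of the chosen mesh part (by convention the skull
#' outer surface) to the target triangulated surface.
#'
#' @param mesh an [fe_mesh].
#' @param surface_part part id whose nodes are measured; `NULL` measures all
#'   shell-element nodes.
#' @param target a [tri_surface].
#' @return An object of class `geometric_error_report` with
#'   `per_node_distance` (named by node id), `mean_error`, `max_error` (mm).
#' @export
surface_distance_error <- function(mesh, surface_part = NULL, target) {
  if (is.null(mesh$shells) || !nrow(mesh$shells))
    stop("mesh has no shell elements to measure")
  sh <- mesh$shells
  if (!is.null(surface_part)) sh <- sh[sh$part == surface_part, , drop = FALSE]
  ids <- unique(stats::na.omit(unlist(sh[paste0("n", 1:4)], use.names = FALSE)))
  if (!length(ids)) stop("empty node selection for surface part ",
                         surface_part)
  pts <- mesh$node_coords[node_index(mesh, ids), , drop = FALSE]
  d <- point_surface_distance(pts, target)
  names(d) <- ids
  structure(list(per_node_distance = d, mean_error = mean(d),
                 max_error = max(d)),
            class = "geometric_error_report")
}

#' @export
print.geometric_error_report <- function(x, ...) {
  cat("<geometric_error_report> ", length(x$per_node_distance),
      " nodes: mean ", sprintf("%.3f", x$mean_error), " mm, max ",
      sprintf("%.3f", x$max_error), " mm\n", sep = "")
  invisible(x)
}

#' Default morph-acceptance gates
#'
#' Mean geometric error < 4 mm, max < 5 mm, mean quality change < 5 %, max
#' change < 10 %, minimum scaled Jacobian > 0.2.
#'
#' @return named list of gate thresholds.
#' @export
default_morph_gates <- function() {
  list(mean_error_mm = 4, max_error_mm = 5,
       mean_change = 0.05, max_change = 0.10, min_jacobian = 0.2)
}

#' Pass/fail verdict for a morphed mesh
#'
#' Applies the acceptance gates to a quality report and a geometric error
#' report. All thresholds are configurable; the verdict lists every failing
#' gate.
#'
#' @param quality a [quality_change_rate] `quality_report`.
#' @param geometry a [surface_distance_error] `geometric_error_report`,
#'   or `NULL` to skip the geometric gates.
#' @param gates named list as from [default_morph_gates].
#' @return list with `pass` (logical) and `failures` (character vector of
#'   failing-gate descriptions).
#' @export
validate_morph <- function(quality, geometry = NULL,
                           gates = default_morph_gates()) {
  fails <- character()
  s <- quality$summary
  if (max(s$mean_change) >= gates$mean_change)
    fails <- c(fails, sprintf(
      "mean quality change %.1f%% >= gate %.1f%%",
      100 * max(s$mean_change), 100 * gates$mean_change))
  if (max(s$max_change) >= gates$max_change)
    fails <- c(fails, sprintf(
      "max quality change %.1f%% >= gate %.1f%%",
      100 * max(s$max_change), 100 * gates$max_change))
  if (min(s$min_jacobian) <= gates$min_jacobian)
    fails <- c(fails, sprintf(
      "min scaled Jacobian %.3f <= gate %.3f",
      min(s$min_jacobian), gates$min_jacobian))
  if (!is.null(geometry)) {
    if (geometry$mean_error >= gates$mean_error_mm)
      fails <- c(fails, sprintf("mean geometric error %.2f mm >= gate %g mm",
                                geometry$mean_error, gates$mean_error_mm))
    if (geometry$max_error >= gates$max_error_mm)
      fails <- c(fails, sprintf("max geometric error %.2f mm >= gate %g mm",
                                geometry$max_error, gates$max_error_mm))
  }
  list(pass = length(fails) == 0L, failures = fails)
}
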