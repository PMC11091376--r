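#' Finite-element mesh container
#'
#' An `fe_mesh` holds the node table and element connectivity of a head
#' finite-element model: shell elements (3- or 4-node, typically the skull
#' surface) and solid elements (4-node tetrahedra or 8-node hexahedra,
#' typically brain tissue), plus an ordered landmark node set used to drive
#' morphing. Coordinates are in millimetres; node and element ids are the
#' 1-based ids of the keyword file they came from.
#'
#' @param node_ids integer vector of unique positive node ids.
#' @param node_coords numeric matrix, one row per node, columns x/y/z (mm).
#' @param shells data.frame with columns `id`, `part`, `n1..n4` (`n4 = NA`
#'   for triangles), or `NULL`.
#' @param solids data.frame with columns `id`, `part`, `n1..n8` (`n5..n8 = NA`
#'   for tetrahedra), or `NULL`.
#' @param landmark_set integer vector of node ids designated as landmarks,
#'   in a fixed order shared with landmark target tables.
#' @param part_labels optional named character vector mapping part id to name.
#' @return An object of class `fe_mesh`.
#' @export
fe_mesh <- function(node_ids, node_coords, shells = NULL, solids = NULL,
                    landmark_set = integer(), part_labels = NULL) {
  node_ids <- as.integer(node_ids)
  node_coords <- as.matrix(node_coords)
  storage.mode(node_coords) <- "double"
  if (ncol(node_coords) != 3L || nrow(node_coords) != length(node_ids))
    stop("node_coords must be an n x 3 matrix matching node_ids")
  colnames(node_coords) <- c("x", "y", "z")
  mesh <- structure(
    list(node_ids = node_ids, node_coords = node_coords,
         shells = shells, solids = solids,
         landmark_set = as.integer(landmark_set),
         part_labels = part_labels),
    class = "fe_mesh")
  validate_fe_mesh(mesh)
  mesh
}

empty_shell_table <- function() {
  data.frame(id = integer(), part = integer(),
             n1 = integer(), n2 = integer(), n3 = integer(), n4 = integer())
}

empty_solid_table <- function() {
  data.frame(id = integer(), part = integer(),
             n1 = integer(), n2 = integer(), n3 = integer(), n4 = integer(),
             n5 = integer(), n6 = integer(), n7 = integer(), n8 = integer())
}

#' Validate an fe_mesh object
#'
#' Checks the structural invariants: unique positive node ids, every element
#' node id present in the node table, shells with 3 or 4 nodes, solids with
#' 4 or 8 nodes, and a duplicate-free landmark set.
#'
#' @param mesh an `fe_mesh`.
#' @return `mesh`, invisibly; errors describe the first violated invariant.
#' @export
validate_fe_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "fe_mesh"))
  ids <- mesh$node_ids
  if (anyDuplicated(ids)) stop("duplicate node id: ", ids[duplicated(ids)][1L])
  if (any(ids <= 0L)) stop("node ids must be positive")
  known <- ids
  check_refs <- function(tab, cols, what) {
    if (is.null(tab) || nrow(tab) == 0L) return(invisible())
    refs <- unlist(tab[cols], use.names = FALSE)
    refs <- refs[!is.na(refs)]
    bad <- setdiff(refs, known)
    if (length(bad))
      stop(what, " references missing node id ", bad[1L])
    if (anyDuplicated(tab$id))
      stop("duplicate ", what, " id: ", tab$id[duplicated(tab$id)][1L])
  }
  check_refs(mesh$shells, paste0("n", 1:4), "shell element")
  check_refs(mesh$solids, paste0("n", 1:8), "solid element")
  if (!is.null(mesh$shells) && nrow(mesh$shells)) {
    nn <- rowSums(!is.na(mesh$shells[paste0("n", 1:4)]))
    if (any(!nn %in% c(3L, 4L)))
      stop("shell element ", mesh$shells$id[which(!nn %in% c(3L, 4L))[1L]],
           " must have 3 or 4 nodes")
  }
  if (!is.null(mesh$solids) && nrow(mesh$solids)) {
    nn <- rowSums(!is.na(mesh$solids[paste0("n", 1:8)]))
    if (any(!nn %in% c(4L, 8L)))
      stop("solid element ", mesh$solids$id[which(!nn %in% c(4L, 8L))[1L]],
           " must have 4 or 8 nodes")
  }
  if (anyDuplicated(mesh$landmark_set))
    stop("landmark_set contains duplicate node ids")
  if (length(mesh$landmark_set) && length(setdiff(mesh$landmark_set, known)))
    stop("landmark_set references missing node id ",
         setdiff(mesh$landmark_set, known)[1L])
  invisible(mesh)
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat("<fe_mesh> ", length(x$node_ids), " nodes, ",
      if (is.null(x$shells)) 0L else nrow(x$shells), " shells, ",
      if (is.null(x$solids)) 0L else nrow(x$solids), " solids, ",
      length(x$landmark_set), " landmarks\n", sep = "")
  if (!is.null(x$part_labels))
    cat("  parts:", paste(names(x$part_labels), x$part_labels,
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# row indices into node table for a vector of node ids (NA-safe)
node_index <- function(mesh, ids) match(ids, mesh$node_ids)

#' Landmark coordinates of a mesh
#'
#' Returns the coordinates of the mesh's landmark node set, in landmark order.
#'
#' @param mesh an `fe_mesh` with a non-empty `landmark_set`.
#' @return m x 3 numeric matrix (mm).
#' @export
landmark_coords <- function(mesh) {
  if (!length(mesh$landmark_set)) stop("mesh has no landmark set")
  mesh$node_coords[node_index(mesh, mesh$landmark_set), , drop = FALSE]
}

#' Triangulated surface container
#'
#' @param vertices numeric v x 3 matrix (mm).
#' @param triangles integer t x 3 matrix of 1-based vertex indices.
#' @param allow_degenerate keep zero-area triangles instead of erroring.
#' @return An object of class `tri_surface`.
#' @export
tri_surface <- function(vertices, triangles, allow_degenerate = FALSE) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles); storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be v x 3")
  if (ncol(triangles) != 3L) stop("triangles must be t x 3")
  if (nrow(triangles) && (min(triangles) < 1L || max(triangles) > nrow(vertices)))
    stop("triangle vertex index out of range")
  if (!allow_degenerate && nrow(triangles)) {
    a <- vertices[triangles[, 1L], , drop = FALSE]
    b <- vertices[triangles[, 2L], , drop = FALSE]
    cc <- vertices[triangles[, 3L], , drop = FALSE]
    ar <- 0.5 * sqrt(rowSums(cross3(b - a, cc - a)^2))
    if (any(ar <= 0))
      stop("degenerate (zero-area) triangle at row ", which(ar <= 0)[1L])
  }
  structure(list(vertices = vertices, triangles = triangles),
            class = "tri_surface")
}

#' @export
print.tri_surface <- function(x, ...) {
  cat("<tri_surface> ", nrow(x$vertices), " vertices, ",
      nrow(x$triangles), " triangles\n", sep = "")
  invisible(x)
}

# row-wise cross product of n x 3 matrices
cross3 <- function(u, v) {
  cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
        u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
        u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
}

#' Subject characteristics
#'
#' The four anthropometric predictors of the shape model: gender (0 = female,
#' 1 = male), age in years, stature in metres and body mass index in kg/m^2.
#'
#' @param gender 0 or 1.
#' @param age years, > 0.
#' @param height metres, in (0.5, 2.5).
#' @param bmi kg/m^2, in (10, 60).
#' @return A one-row data.frame of class `subject_characteristics`.
#' @export
subject_characteristics <- function(gender, age, height, bmi) {
  if (!all(gender %in% c(0, 1))) stop("gender must be coded 0 (female) / 1 (male)")
  if (any(age <= 0)) stop("age must be positive")
  if (any(height <= 0.5 | height >= 2.5)) stop("height (m) out of range (0.5, 2.5)")
  if (any(bmi <= 10 | bmi >= 60)) stop("bmi out of range (10, 60)")
  structure(data.frame(gender = gender, age = age, height = height, bmi = bmi),
            class = c("subject_characteristics", "data.frame"))
}

#' Time-history signal
#'
#' @param times strictly increasing numeric vector (s).
#' @param values numeric vector, same length.
#' @return An object of class `hm_signal`.
#' @export
hm_signal <- function(times, values) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) stop("times and values lengths differ")
  if (length(times) < 2L) stop("a signal needs at least 2 samples")
  if (any(diff(times) <= 0)) stop("time axis must be strictly increasing")
  structure(list(times = times, values = values), class = "hm_signal")
}

#' @export
print.hm_signal <- function(x, ...) {
  cat("<hm_signal> ", length(x$times), " samples over [",
      format(x$times[1L]), ", ", format(x$times[length(x$times)]), "] s\n",
      sep = "")
  invisible(x)
}
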