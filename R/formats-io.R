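#' Read a finite-element mesh from a keyword-style text file
#'
#' Parses a minimal subset of the LS-DYNA keyword format: `*NODE`,
#' `*ELEMENT_SHELL`, `*ELEMENT_SOLID` and `*SET_NODE_LIST` blocks, in free
#' (comma- or whitespace-separated) format. Comment lines starting with `$`
#' and unknown keyword blocks are skipped; a skipped block raises a warning
#' naming the keyword. Triangular shells may be written either with three
#' node fields or LS-DYNA style with the fourth node repeating the third;
#' tetrahedra likewise with four fields or with `n5..n8` repeating `n4`.
#' The first `*SET_NODE_LIST` block is taken as the landmark set, in file
#' order.
#'
#' @param path file to read.
#' @param dialect `"keyword"` (the only dialect currently implemented;
#'   `"generic"` is accepted as an alias).
#' @return An [fe_mesh].
#' @export
read_mesh <- function(path, dialect = c("keyword", "generic")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nodes <- list(); shells <- list(); solids <- list(); lmset <- integer()
  seen_set <- FALSE
  block <- "none"
  known <- c("*NODE", "*ELEMENT_SHELL", "*ELEMENT_SOLID", "*SET_NODE_LIST",
             "*KEYWORD", "*END")
  set_skip_header <- FALSE
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "$")) next
    if (startsWith(ln, "*")) {
      kw <- toupper(strsplit(ln, "[[:space:]]")[[1L]][1L])
      if (kw %in% c("*KEYWORD", "*END")) { block <- "none"; next }
      if (kw == "*NODE") block <- "node"
      else if (startsWith(kw, "*ELEMENT_SHELL")) block <- "shell"
      else if (startsWith(kw, "*ELEMENT_SOLID")) block <- "solid"
      else if (startsWith(kw, "*SET_NODE_LIST")) {
        if (seen_set) { block <- "skip" }
        else { block <- "set"; seen_set <- TRUE; set_skip_header <- TRUE }
      } else {
        warning("skipping unknown keyword block ", kw, " at line ", i)
        block <- "skip"
      }
      next
    }
    toks <- strsplit(ln, "[,[:space:]]+")[[1L]]
    toks <- toks[nzchar(toks)]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals) && block %in% c("node", "shell", "solid"))
      stop("parse failure at line ", i, ": non-numeric field in ", block,
           " block")
    if (block == "node") {
      if (length(vals) < 4L) stop("parse failure at line ", i,
                                  ": node line needs id,x,y,z")
      nodes[[length(nodes) + 1L]] <- vals[1:4]
    } else if (block == "shell") {
      if (length(vals) < 5L) stop("parse failure at line ", i,
                                  ": shell line needs id,part,n1..n3")
      n <- c(vals[3:5], if (length(vals) >= 6L) vals[6L] else NA_real_)
      if (!is.na(n[4L]) && (n[4L] == n[3L] || n[4L] == 0)) n[4L] <- NA_real_
      shells[[length(shells) + 1L]] <- c(vals[1:2], n)
    } else if (block == "solid") {
      if (length(vals) < 6L) stop("parse failure at line ", i,
                                  ": solid line needs id,part,n1..n4")
      n <- c(vals[3:6], rep(NA_real_, 4L))
      if (length(vals) >= 10L) {
        rest <- vals[7:10]
        if (!all(rest == vals[6L]) && !all(rest == 0)) n[5:8] <- rest
      }
      solids[[length(solids) + 1L]] <- c(vals[1:2], n)
    } else if (block == "set") {
      if (set_skip_header) { set_skip_header <- FALSE; next }  # set id card
      if (anyNA(vals)) stop("parse failure at line ", i,
                            ": non-numeric node id in set block")
      lmset <- c(lmset, as.integer(vals[vals != 0]))
    }
  }
  if (!length(nodes)) stop("no *NODE block found in ", path)
  nm <- do.call(rbind, nodes)
  sh <- if (length(shells)) {
    m <- do.call(rbind, shells)
    data.frame(id = as.integer(m[, 1L]), part = as.integer(m[, 2L]),
               n1 = as.integer(m[, 3L]), n2 = as.integer(m[, 4L]),
               n3 = as.integer(m[, 5L]), n4 = as.integer(m[, 6L]))
  } else NULL
  so <- if (length(solids)) {
    m <- do.call(rbind, solids)
    data.frame(id = as.integer(m[, 1L]), part = as.integer(m[, 2L]),
               n1 = as.integer(m[, 3L]), n2 = as.integer(m[, 4L]),
               n3 = as.integer(m[, 5L]), n4 = as.integer(m[, 6L]),
               n5 = as.integer(m[, 7L]), n6 = as.integer(m[, 8L]),
               n7 = as.integer(m[, 9L]), n8 = as.integer(m[, 10L]))
  } else NULL
  fe_mesh(node_ids = as.integer(nm[, 1L]),
          node_coords = nm[, 2:4, drop = FALSE],
          shells = sh, solids = so, landmark_set = lmset)
}

#' Write a finite-element mesh to a keyword-style text file
#'
#' Emits the minimal keyword subset read by [read_mesh]: nodes, shell and
#' solid elements and the landmark node set. Coordinates are printed with
#' 10 significant digits so a read/write round trip reproduces them to
#' better than 1e-6 mm at head scale.
#'
#' @param mesh an [fe_mesh].
#' @param path output file.
#' @param dialect as in [read_mesh].
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, dialect = c("keyword", "generic")) {
  dialect <- match.arg(dialect)
  validate_fe_mesh(mesh)
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to ", path)
  on.exit(close(con))
  out <- c("*KEYWORD", "*NODE")
  out <- c(out, sprintf("%d, %.10g, %.10g, %.10g", mesh$node_ids,
                        mesh$node_coords[, 1L], mesh$node_coords[, 2L],
                        mesh$node_coords[, 3L]))
  if (!is.null(mesh$shells) && nrow(mesh$shells)) {
    s <- mesh$shells
    n4 <- ifelse(is.na(s$n4), s$n3, s$n4)  # tri written LS-DYNA style n4=n3
    out <- c(out, "*ELEMENT_SHELL",
             sprintf("%d, %d, %d, %d, %d, %d", s$id, s$part, s$n1, s$n2,
                     s$n3, n4))
  }
  if (!is.null(mesh$solids) && nrow(mesh$solids)) {
    s <- mesh$solids
    tet <- is.na(s$n5)
    n5 <- ifelse(tet, s$n4, s$n5); n6 <- ifelse(tet, s$n4, s$n6)
    n7 <- ifelse(tet, s$n4, s$n7); n8 <- ifelse(tet, s$n4, s$n8)
    out <- c(out, "*ELEMENT_SOLID",
             sprintf("%d, %d, %d, %d, %d, %d, %d, %d, %d, %d",
                     s$id, s$part, s$n1, s$n2, s$n3, s$n4, n5, n6, n7, n8))
  }
  if (length(mesh$landmark_set)) {
    out <- c(out, "*SET_NODE_LIST", "1")
    idx <- mesh$landmark_set
    pad <- c(idx, rep(0L, (8L - length(idx) %% 8L) %% 8L))
    rows <- matrix(pad, ncol = 8L, byrow = TRUE)
    out <- c(out, apply(rows, 1L, paste, collapse = ", "))
  }
  out <- c(out, "*END")
  writeLines(out, con)
  invisible(path)
}

#' Read per-subject landmark tables with characteristics
#'
#' Long-format CSV: one row per subject and landmark, columns
#' `subject_id, gender, age, height, bmi, landmark, x, y, z`. Every subject
#' must carry the same landmark count; landmarks are ordered by the
#' `landmark` index.
#'
#' @param path CSV file.
#' @return A list with `subjects` (character ids), `characteristics`
#'   (n x 4 data.frame: gender, age, height, bmi) and `landmarks`
#'   (list of m x 3 matrices, one per subject).
#' @export
read_landmark_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "gender", "age", "height", "bmi",
            "landmark", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("landmark table missing columns: ",
                         paste(miss, collapse = ", "))
  num <- c("gender", "age", "height", "bmi", "landmark", "x", "y", "z")
  for (cl in num) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    if (anyNA(v) && !anyNA(df[[cl]]))
      stop("non-numeric values in column ", cl)
    if (anyNA(v)) stop("missing/non-numeric values in column ", cl)
    df[[cl]] <- v
  }
  ids <- unique(df$subject_id)
  counts <- table(df$subject_id)
  if (length(unique(as.integer(counts))) != 1L)
    stop("ragged landmark counts across subjects: ",
         paste(names(counts)[c(1L, which(counts != counts[1L])[1L])],
               collapse = " vs "))
  lms <- vector("list", length(ids))
  chars <- data.frame(gender = numeric(length(ids)), age = numeric(length(ids)),
                      height = numeric(length(ids)), bmi = numeric(length(ids)))
  for (i in seq_along(ids)) {
    sub <- df[df$subject_id == ids[i], , drop = FALSE]
    sub <- sub[order(sub$landmark), , drop = FALSE]
    lms[[i]] <- as.matrix(sub[, c("x", "y", "z")])
    dimnames(lms[[i]]) <- NULL
    chars[i, ] <- sub[1L, c("gender", "age", "height", "bmi")]
  }
  list(subjects = as.character(ids), characteristics = chars, landmarks = lms)
}

#' Write per-subject landmark tables with characteristics
#'
#' Inverse of [read_landmark_table].
#'
#' @param subjects character vector of subject ids.
#' @param characteristics n x 4 data.frame (gender, age, height, bmi).
#' @param landmarks list of m x 3 matrices.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_landmark_table <- function(subjects, characteristics, landmarks, path) {
  stopifnot(length(subjects) == nrow(characteristics),
            length(subjects) == length(landmarks))
  m <- nrow(landmarks[[1L]])
  rows <- lapply(seq_along(subjects), function(i) {
    lm <- landmarks[[i]]
    data.frame(subject_id = subjects[i],
               gender = characteristics$gender[i], age = characteristics$age[i],
               height = characteristics$height[i], bmi = characteristics$bmi[i],
               landmark = seq_len(m), x = lm[, 1L], y = lm[, 2L], z = lm[, 3L])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a two-column time,value signal CSV
#'
#' @param path CSV with columns `time` and `value` (header required).
#' @return An [hm_signal]; errors on non-monotone time or < 2 samples.
#' @export
read_signal <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2L) stop("signal CSV needs time and value columns")
  hm_signal(df[[1L]], df[[2L]])
}

#' Write a signal to CSV
#' @param sig an [hm_signal].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_signal <- function(sig, path) {
  utils::write.csv(data.frame(time = sig$times, value = sig$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a triangulated surface (ASCII/binary STL or OBJ)
#'
#' Format is chosen from the file extension (`.stl`, `.obj`); STL flavour
#' (ascii vs binary) is auto-detected. STL files carry no shared-vertex
#' topology, so identical vertex coordinates are merged on read.
#'
#' @param path surface file.
#' @return A [tri_surface].
#' @export
read_surface <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "obj") return(read_obj(path))
  if (ext != "stl") stop("unsupported surface format: .", ext)
  # ascii STL starts with "solid" AND contains "facet"; binary otherwise
  head_raw <- readBin(path, "raw", n = 512L)
  head_txt <- rawToChar(head_raw[head_raw != as.raw(0L)])
  if (grepl("^\\s*solid", head_txt) && grepl("facet", head_txt))
    read_stl_ascii(path) else read_stl_binary(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (!length(vl) || !length(fl)) stop("no vertices/faces in OBJ ", path)
  verts <- do.call(rbind, lapply(strsplit(vl, "[[:space:]]+"), function(t)
    as.numeric(t[2:4])))
  tris <- do.call(rbind, lapply(strsplit(fl, "[[:space:]]+"), function(t) {
    idx <- as.integer(sub("/.*", "", t[-1L]))
    if (length(idx) != 3L) stop("non-triangular face in OBJ ", path)
    idx
  }))
  tri_surface(verts, tris)
}

read_stl_ascii <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vl <- lines[startsWith(lines, "vertex")]
  if (length(vl) %% 3L != 0L) stop("corrupt ascii STL: vertex count not /3")
  verts <- do.call(rbind, lapply(strsplit(vl, "[[:space:]]+"), function(t)
    as.numeric(t[2:4])))
  merge_stl_soup(verts)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nt <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  verts <- matrix(0, nrow = 3L * nt, ncol = 3L)
  for (t in seq_len(nt)) {
    dat <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    verts[(3L * t - 2L):(3L * t), ] <- matrix(dat[4:12], 3L, 3L, byrow = TRUE)
    readBin(con, "raw", n = 2L)
  }
  merge_stl_soup(verts)
}

merge_stl_soup <- function(verts) {
  key <- apply(verts, 1L, paste, collapse = "|")
  uid <- match(key, unique(key))
  uverts <- verts[!duplicated(key), , drop = FALSE]
  tris <- matrix(uid, ncol = 3L, byrow = TRUE)
  tri_surface(uverts, tris, allow_degenerate = TRUE)
}

#' Write a triangulated surface (ASCII STL or OBJ)
#'
#' @param surf a [tri_surface].
#' @param path output file; `.stl` writes ascii STL, `.obj` Wavefront OBJ.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surf, path) {
  ext <- tolower(tools::file_ext(path))
  v <- surf$vertices; tr <- surf$triangles
  if (ext == "obj") {
    out <- c(sprintf("v %.10g %.10g %.10g", v[, 1L], v[, 2L], v[, 3L]),
             sprintf("f %d %d %d", tr[, 1L], tr[, 2L], tr[, 3L]))
    writeLines(out, path)
  } else if (ext == "stl") {
    a <- v[tr[, 1L], , drop = FALSE]; b <- v[tr[, 2L], , drop = FALSE]
    cc <- v[tr[, 3L], , drop = FALSE]
    n <- cross3(b - a, cc - a)
    len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
    n <- n / len
    chunks <- vapply(seq_len(nrow(tr)), function(i) paste(
      sprintf(" facet normal %.10g %.10g %.10g", n[i, 1L], n[i, 2L], n[i, 3L]),
      "  outer loop",
      sprintf("   vertex %.10g %.10g %.10g", a[i, 1L], a[i, 2L], a[i, 3L]),
      sprintf("   vertex %.10g %.10g %.10g", b[i, 1L], b[i, 2L], b[i, 3L]),
      sprintf("   vertex %.10g %.10g %.10g", cc[i, 1L], cc[i, 2L], cc[i, 3L]),
      "  endloop", " endfacet", sep = "\n"), character(1L))
    writeLines(c("solid surface", chunks, "endsolid surface"), path)
  } else stop("unsupported surface format: .", ext)
  invisible(path)
}
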