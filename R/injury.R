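#' Injury-degree class boundaries (kPa)
#'
#' Lower bounds of the five head-injury degrees on peak brain-tissue
#' von Mises stress: J1 minor injury, J2 cerebral contusion, J3 moderate
#' injury, J4 cerebral concussion, J5 severe injury. Intervals are half-open
#' `[lo, hi)`: a value exactly on a printed boundary (6, 11, 15, 27 kPa)
#' belongs to the upper class.
#'
#' @return named numeric vector of class lower bounds.
#' @export
injury_class_bounds <- function() {
  c(J1 = 0, J2 = 6, J3 = 11, J4 = 15, J5 = 27)
}

#' Classify peak brain von Mises stress into injury degree J1-J5
#'
#' @param von_mises numeric vector of peak brain-tissue von Mises stress in
#'   kPa; must be non-negative.
#' @return factor with levels `J1 ... J5`.
#' @export
classify_injury <- function(von_mises) {
  if (any(is.na(von_mises))) stop("von Mises values must not be missing")
  if (any(von_mises < 0)) stop("von Mises stress must be non-negative")
  bounds <- injury_class_bounds()
  cut(von_mises, breaks = c(unname(bounds), Inf), labels = names(bounds),
      right = FALSE)
}

#' Assemble an injury dataset
#'
#' @param records data.frame with columns `gender`, `age`, `height`, `bmi`,
#'   `state` (0 = pedestrian, 1 = cyclist), `speed_kmh`, `von_mises_kpa`.
#'   The `injury_class` column is (re)derived with [classify_injury].
#' @param design_meta optional list describing the generating design (grid,
#'   seed).
#' @return data.frame of class `injury_dataset`.
#' @export
injury_dataset <- function(records, design_meta = NULL) {
  need <- c("gender", "age", "height", "bmi", "state", "speed_kmh",
            "von_mises_kpa")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("injury records missing columns: ",
                         paste(miss, collapse = ", "))
  if (!nrow(records)) stop("injury dataset must be non-empty")
  if (!all(records$state %in% c(0, 1)))
    stop("state must be coded 0 (pedestrian) / 1 (cyclist)")
  if (any(records$von_mises_kpa <= 0))
    stop("von Mises stress must be positive")
  records$injury_class <- classify_injury(records$von_mises_kpa)
  structure(records, class = c("injury_dataset", "data.frame"),
            design_meta = design_meta)
}

#' Read / write the injury dataset CSV schema
#'
#' Columns: `subject_id, gender, age, height, bmi, state, speed_kmh,
#' von_mises_kpa, injury_class`.
#'
#' @param path CSV file.
#' @return [injury_dataset] for `read_injury_dataset`; `path` invisibly for
#'   `write_injury_dataset`.
#' @export
read_injury_dataset <- function(path) {
  injury_dataset(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_injury_dataset
#' @param ds an [injury_dataset].
#' @export
write_injury_dataset <- function(ds, path) {
  df <- as.data.frame(ds)
  if (!"subject_id" %in% names(df)) df$subject_id <- seq_len(nrow(df))
  utils::write.csv(
    df[, c("subject_id", "gender", "age", "height", "bmi", "state",
           "speed_kmh", "von_mises_kpa", "injury_class")],
    path, row.names = FALSE)
  invisible(path)
}

band_label <- function(x, breaks, labels) {
  cut(x, breaks = breaks, labels = labels, right = FALSE,
      include.lowest = TRUE)
}

#' Summary tables for an injury dataset
#'
#' Reproduces the study-style descriptive views: per-speed von Mises mean
#' and central 90 % interval; injury-class share distributions binned by
#' height (< 1.7 / >= 1.7 m), gender, age decade and 5-unit BMI band; and
#' the pedestrian-vs-cyclist mean response comparison. Empty bins are
#' absent from the tables, not reported as zero rows.
#'
#' @param ds an [injury_dataset].
#' @return list of data.frames: `by_speed`, `class_by_height`,
#'   `class_by_gender`, `class_by_age`, `class_by_bmi`, `by_state`.
#' @export
dataset_summary <- function(ds) {
  stopifnot(nrow(ds) > 0L)
  vm <- ds$von_mises_kpa
  by_speed <- do.call(rbind, lapply(split(vm, ds$speed_kmh), function(v)
    data.frame(mean = mean(v), lo90 = unname(stats::quantile(v, 0.05)),
               hi90 = unname(stats::quantile(v, 0.95)), n = length(v))))
  by_speed <- cbind(speed_kmh = as.numeric(rownames(by_speed)), by_speed)
  rownames(by_speed) <- NULL

  class_share <- function(groups) {
    groups <- droplevels(factor(groups))
    tab <- table(groups, ds$injury_class)
    share <- prop.table(tab, margin = 1L)
    df <- as.data.frame.matrix(share)
    cbind(group = rownames(df), df, n = as.integer(rowSums(tab)))
  }
  out <- list(
    by_speed = by_speed,
    class_by_height = class_share(band_label(
      ds$height, c(-Inf, 1.7, Inf), c("<1.7m", ">=1.7m"))),
    class_by_gender = class_share(ifelse(ds$gender == 0, "female", "male")),
    class_by_age = class_share(band_label(
      ds$age, seq(0, 110, by = 10),
      paste0(seq(0, 100, by = 10), "-", seq(10, 110, by = 10)))),
    class_by_bmi = class_share(band_label(
      ds$bmi, seq(10, 60, by = 5),
      paste0(seq(10, 55, by = 5), "-", seq(15, 60, by = 5)))),
    by_state = data.frame(
      state = c("pedestrian", "cyclist"),
      mean_von_mises = c(mean(vm[ds$state == 0]), mean(vm[ds$state == 1])),
      n = c(sum(ds$state == 0), sum(ds$state == 1))))
  rownames(out$by_state) <- NULL
  out
}

#' Severe-injury share difference between two bands of a characteristic
#'
#' Percentage-point difference in J5 (severe injury) prevalence between two
#' value bands of one characteristic column — the quantity used to describe
#' age and BMI effects on severe injury risk.
#'
#' @param ds an [injury_dataset].
#' @param column characteristic column name (e.g. `"age"`, `"bmi"`).
#' @param band_a,band_b numeric length-2 ranges `[lo, hi)`; the result is
#'   share(band_a) - share(band_b) in percentage points.
#' @return numeric difference in percentage points.
#' @export
severe_share_gap <- function(ds, column, band_a, band_b) {
  x <- ds[[column]]
  share <- function(band) {
    sel <- x >= band[1L] & x < band[2L]
    if (!any(sel)) stop("empty band [", band[1L], ", ", band[2L],
                        ") for column ", column)
    100 * mean(ds$injury_class[sel] == "J5")
  }
  share(band_a) - share(band_b)
}
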