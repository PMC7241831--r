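#' Per-branch tracheal radius measurement tables
#'
#' A `measurement_table` is a validated data frame of per-branch radius
#' records with columns `individual_id`, `species`, `level`, `branch_path`
#' and `radius_um`, one row per measured branch. Branch identity within an
#' individual is encoded by `branch_path`: the level-1 (primary) branch is
#' `"1"`; its level-2 children are `"2a"`, `"2b"`, `"2c"`, `"2d"`; level-3
#' children of the level-2 branches `a` and `b` are `"3a1"`, `"3a2"`, ...,
#' `"3b1"`, ... so the parent of every branch is recoverable from its path.
#'
#' Structural invariants (checked by [validate_measurements()]):
#' * every radius is positive;
#' * `level` equals the depth encoded by `branch_path`;
#' * the parent path of every non-level-1 record exists in the same
#'   individual;
#' * each individual has exactly one level-1 record and 2-4 level-2
#'   children;
#' * at most two level-2 branches (`a` and `b`) carry level-3 children.
#'
#' @param x a data frame with the five required columns.
#' @param provenance free-text metadata recorded as an attribute (source
#'   file, generator seed, ...).
#' @return `as_measurement_table()` returns `x` with class
#'   `measurement_table` and a `provenance` attribute; it stops with the
#'   collected validation messages if any invariant fails.
#' @seealso [read_measurement_table()], [extract_events()],
#'   [generate_dataset()]
#' @export
as_measurement_table <- function(x, provenance = "unspecified") {
  x <- as.data.frame(x)
  problems <- validate_measurements(x)
  if (length(problems) > 0L) {
    stop("invalid measurement table:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  x$individual_id <- as.character(x$individual_id)
  x$species <- as.character(x$species)
  x$level <- as.integer(x$level)
  class(x) <- c("measurement_table", "data.frame")
  attr(x, "provenance") <- provenance
  x
}

#' Validate the structure of a measurement data frame
#'
#' @param x a data frame.
#' @return a character vector of human-readable problems, each naming the
#'   offending row(s); `character(0)` if the table is valid.
#' @export
validate_measurements <- function(x) {
  required <- c("individual_id", "species", "level", "branch_path", "radius_um")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    return(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  problems <- character(0)
  if (nrow(x) == 0L) return(problems)

  bad_radius <- which(!is.finite(x$radius_um) | x$radius_um <= 0)
  if (length(bad_radius) > 0L) {
    problems <- c(problems, sprintf(
      "non-positive radius at row(s) %s", paste(bad_radius, collapse = ", ")))
  }
  path_lv <- branch_path_level(x$branch_path)
  bad_path <- which(is.na(path_lv))
  if (length(bad_path) > 0L) {
    problems <- c(problems, sprintf(
      "unparseable branch_path at row(s) %s", paste(bad_path, collapse = ", ")))
  }
  mismatch <- which(!is.na(path_lv) & path_lv != x$level)
  if (length(mismatch) > 0L) {
    problems <- c(problems, sprintf(
      "level does not match branch_path depth at row(s) %s",
      paste(mismatch, collapse = ", ")))
  }
  if (length(problems) > 0L) return(problems)

  for (id in unique(x$individual_id)) {
    sub <- x[x$individual_id == id, , drop = FALSE]
    if (anyDuplicated(sub$branch_path)) {
      problems <- c(problems, sprintf(
        "individual %s: duplicated branch_path(s) %s", id,
        paste(unique(sub$branch_path[duplicated(sub$branch_path)]), collapse = ", ")))
    }
    n1 <- sum(sub$level == 1L)
    if (n1 != 1L) {
      problems <- c(problems, sprintf(
        "individual %s: %d level-1 records (expected exactly 1)", id, n1))
    }
    n2 <- sum(sub$level == 2L)
    if (n1 == 1L && (n2 < 2L || n2 > 4L)) {
      problems <- c(problems, sprintf(
        "individual %s: %d level-2 children (expected 2-4)", id, n2))
    }
    parents <- branch_path_parent(sub$branch_path)
    orphan <- !is.na(parents) & !(parents %in% sub$branch_path)
    if (any(orphan)) {
      problems <- c(problems, sprintf(
        "individual %s: orphan branch_path(s) %s (parent missing)", id,
        paste(sub$branch_path[orphan], collapse = ", ")))
    }
    l3_parents <- unique(parents[sub$level == 3L])
    if (length(l3_parents) > 2L) {
      problems <- c(problems, sprintf(
        "individual %s: level-3 children under %d level-2 branches (at most 2)",
        id, length(l3_parents)))
    }
  }
  problems
}

## depth encoded by a branch path; NA if the grammar does not match
branch_path_level <- function(path) {
  path <- as.character(path)
  lv <- rep(NA_integer_, length(path))
  lv[grepl("^1$", path)] <- 1L
  lv[grepl("^2[a-d]$", path)] <- 2L
  lv[grepl("^3[ab][1-9]$", path)] <- 3L
  lv
}

## parent path, NA for level-1 records
branch_path_parent <- function(path) {
  path <- as.character(path)
  lv <- branch_path_level(path)
  parent <- rep(NA_character_, length(path))
  parent[lv == 2L] <- "1"
  parent[lv == 3L] <- paste0("2", substr(path[lv == 3L], 2L, 2L))
  parent
}

#' Read a measurement table from a delimited text file
#'
#' Expects a comma-separated UTF-8 file with header
#' `individual_id,species,level,branch_path,radius_um` and `.` as decimal
#' separator. If the file records diameters instead of radii (the raw
#' measurement is the largest internal wall-to-wall distance), pass
#' `values = "diameter"` and each value is halved on read.
#'
#' @param path file path or connection.
#' @param values `"radius"` (default) or `"diameter"`.
#' @return a [as_measurement_table()] object.
#' @export
read_measurement_table <- function(path, values = c("radius", "diameter")) {
  values <- match.arg(values)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("individual_id", "species", "level", "branch_path", "radius_um")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("measurement file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (values == "diameter") df$radius_um <- df$radius_um / 2
  src <- if (is.character(path)) path else "connection"
  as_measurement_table(df, provenance = paste0("file:", src))
}

#' Write a measurement table as CSV
#'
#' Emits the same dialect [read_measurement_table()] consumes, so
#' write-then-read is the identity on valid tables.
#'
#' @param table a `measurement_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_measurement_table <- function(table, path) {
  stopifnot(inherits(table, "measurement_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.measurement_table <- function(x, ...) {
  cat(sprintf("measurement_table: %d records, %d individuals, %d species\n",
              nrow(x), length(unique(x$individual_id)),
              length(unique(x$species))))
  cat(sprintf("provenance: %s\n", attr(x, "provenance")))
  NextMethod()
}

#' Convert pixel measurements to micrometres
#'
#' Tomographic measurements are taken in pixels and converted to physical
#' length with the image resolution (7.6 um per pixel for the synchrotron
#' data this package was written around).
#'
#' @param value pixel count(s), non-negative.
#' @param scale micrometres per pixel.
#' @return `value * scale`, in micrometres.
#' @export
pixel_to_micron <- function(value, scale = 7.6) {
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("pixel values must be finite and non-negative", call. = FALSE)
  }
  value * scale
}

#' Compare two measurement passes of the same branches
#'
#' Measurement repeatability QC: pairs the records of two tables by
#' `(individual_id, branch_path)` and summarises the per-measurement
#' differences. Pairs whose absolute difference exceeds `threshold`
#' (default 0.15 um, well below a 7.6 um pixel) are flagged.
#'
#' @param first,second `measurement_table`s with identical record keys.
#' @param threshold flagging threshold in micrometres.
#' @return a list of class `repeatability_report`: `differences` (one row
#'   per pair with `diff_um = second - first`), `mean_abs_difference`,
#'   `max_abs_difference`, `n_flagged`, `flagged`.
#' @export
repeatability_check <- function(first, second, threshold = 0.15) {
  key <- function(t) paste(t$individual_id, t$branch_path, sep = "\r")
  k1 <- key(first); k2 <- key(second)
  unmatched <- c(setdiff(k1, k2), setdiff(k2, k1))
  if (length(unmatched) > 0L) {
    stop("unmatched records: ",
         paste(gsub("\r", "/", unmatched), collapse = ", "), call. = FALSE)
  }
  m <- match(k1, k2)
  diffs <- data.frame(
    individual_id = first$individual_id,
    branch_path = first$branch_path,
    first_um = first$radius_um,
    second_um = second$radius_um[m],
    diff_um = second$radius_um[m] - first$radius_um,
    stringsAsFactors = FALSE
  )
  diffs$flagged <- abs(diffs$diff_um) > threshold
  out <- list(
    differences = diffs,
    mean_abs_difference = mean(abs(diffs$diff_um)),
    max_abs_difference = if (nrow(diffs)) max(abs(diffs$diff_um)) else 0,
    threshold = threshold,
    n_flagged = sum(diffs$flagged),
    flagged = diffs[diffs$flagged, , drop = FALSE]
  )
  class(out) <- "repeatability_report"
  out
}

#' @export
print.repeatability_report <- function(x, ...) {
  cat(sprintf(
    "repeatability: %d pairs, mean |diff| %.4g um, max |diff| %.4g um, %d flagged (> %.3g um)\n",
    nrow(x$differences), x$mean_abs_difference, x$max_abs_difference,
    x$n_flagged, x$threshold))
  invisible(x)
}
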