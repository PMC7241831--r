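#' Branching events
#'
#' A `branching_event` is the unit of branching-exponent estimation: one
#' parent radius together with the radii of its 2-4 immediate children,
#' labelled by the event class it came from (`"L1_2"`: primary branch to
#' its level-2 children; `"L2a_3"` / `"L2b_3"`: the designated level-2
#' branches a and b to their level-3 children).
#'
#' @param parent_radius parent radius, um.
#' @param child_radii numeric vector of 2-4 child radii, um.
#' @param event_class one of `"L1_2"`, `"L2a_3"`, `"L2b_3"`.
#' @param individual_id optional identifier carried through summaries.
#' @return a list of class `branching_event`.
#' @export
branching_event <- function(parent_radius, child_radii,
                            event_class = c("L1_2", "L2a_3", "L2b_3"),
                            individual_id = NA_character_) {
  event_class <- match.arg(event_class)
  if (!is.numeric(parent_radius) || length(parent_radius) != 1L ||
      !is.finite(parent_radius) || parent_radius <= 0) {
    stop("parent_radius must be a single positive number", call. = FALSE)
  }
  if (length(child_radii) < 2L || length(child_radii) > 4L) {
    stop("an event needs 2-4 child radii, got ", length(child_radii),
         call. = FALSE)
  }
  if (any(!is.finite(child_radii)) || any(child_radii <= 0)) {
    stop("child radii must be positive", call. = FALSE)
  }
  structure(
    list(parent_radius = parent_radius,
         child_radii = as.numeric(child_radii),
         event_class = event_class,
         individual_id = as.character(individual_id)),
    class = "branching_event")
}

#' @export
print.branching_event <- function(x, ...) {
  cat(sprintf("branching_event [%s] parent %.4g um -> children %s um\n",
              x$event_class, x$parent_radius,
              paste(signif(x$child_radii, 4), collapse = ", ")))
  invisible(x)
}

#' Extract branching events from a measurement table
#'
#' Builds one event per individual per requested class where all required
#' radii are present: the level-1 parent with its level-2 children
#' (`"L1_2"`), and the level-2 branches `a` and `b` with their level-3
#' children (`"L2a_3"`, `"L2b_3"`). Individuals lacking the parent or
#' having fewer than two children in a class are skipped, not failed; the
#' skip count per class is returned as the `"skipped"` attribute. This
#' per-class skipping is what lets the three event classes have different
#' sample sizes.
#'
#' @param table a `measurement_table`.
#' @param event_class one of `"L1_2"`, `"L2a_3"`, `"L2b_3"`.
#' @return a list of [branching_event()] objects with attribute `skipped`
#'   (number of individuals without a complete event of this class).
#' @export
extract_events <- function(table, event_class = c("L1_2", "L2a_3", "L2b_3")) {
  stopifnot(inherits(table, "measurement_table"))
  event_class <- match.arg(event_class)
  parent_path <- switch(event_class, L1_2 = "1", L2a_3 = "2a", L2b_3 = "2b")
  child_re <- switch(event_class,
                     L1_2 = "^2[a-d]$", L2a_3 = "^3a[1-9]$", L2b_3 = "^3b[1-9]$")
  events <- list()
  skipped <- 0L
  for (id in unique(table$individual_id)) {
    sub <- table[table$individual_id == id, , drop = FALSE]
    parent <- sub$radius_um[sub$branch_path == parent_path]
    kids_idx <- grepl(child_re, sub$branch_path)
    kids <- sub$radius_um[kids_idx][order(sub$branch_path[kids_idx])]
    if (length(parent) != 1L || length(kids) < 2L) {
      skipped <- skipped + 1L
      next
    }
    events[[length(events) + 1L]] <-
      branching_event(parent, kids, event_class, individual_id = id)
  }
  attr(events, "skipped") <- skipped
  events
}

#' Extract every event of every class from a table
#'
#' Convenience wrapper over [extract_events()] for all three classes;
#' used by the pooled per-individual exponent fit and the regression
#' grid.
#'
#' @param table a `measurement_table`.
#' @return a flat list of `branching_event`s.
#' @export
extract_all_events <- function(table) {
  out <- list()
  for (cl in c("L1_2", "L2a_3", "L2b_3")) {
    out <- c(out, extract_events(table, cl))
  }
  out
}
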