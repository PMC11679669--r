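#' Marker displacement over a window
#'
#' The deviation a rater notes from a tracked landmark: the max-min
#' excursion along each axis over the scored window, combined by the
#' Pythagorean theorem, `sqrt(despl_x^2 + despl_y^2)` in cm.
#'
#' @param track A [marker_track()] (positions in cm).
#' @param window Integer sample indices; `NULL` uses the full track.
#' @param deviation `"range"` (max-min excursion, default) or
#'   `"max_from_start"` (largest distance of either axis from its first
#'   sample).
#' @return Displacement in cm.
#' @examples
#' tr <- marker_track("umbilicus", x = c(0, 3, 1), y = c(0, 0, 4))
#' marker_displacement(tr) # 3-4-5 triangle: 5 cm
#' @export
marker_displacement <- function(track, window = NULL,
                                deviation = c("range", "max_from_start")) {
  stopifnot(inherits(track, "marker_track"))
  deviation <- match.arg(deviation)
  if (is.null(window)) window <- seq_along(track$x)
  if (length(window) == 0) stop("window is empty", call. = FALSE)
  x <- track$x[window]
  y <- track$y[window]
  if (deviation == "range") {
    dx <- max(x) - min(x)
    dy <- max(y) - min(y)
  } else {
    dx <- max(abs(x - x[1]))
    dy <- max(abs(y - y[1]))
  }
  sqrt(dx^2 + dy^2)
}

#' Movement of one exercise from its three scoring markers
#'
#' Sums the displacements of the acromion, umbilicus and trochanter markers.
#' An L3 track may be supplied (the dorsal camera records it) and is
#' reported, but it does not enter the sum: only the three named landmarks
#' score.
#'
#' @param tracks A list of [marker_track()]s containing at least the three
#'   scoring markers.
#' @param window Integer sample indices; `NULL` uses full tracks.
#' @param exercise_id Protocol slot (1-14), carried through to reports.
#' @param deviation Passed to [marker_displacement()].
#' @return An object of class `exercise_movement` with `per_marker`
#'   displacements (cm), their sum `mvt`, and any `l3` displacement.
#' @export
exercise_movement <- function(tracks, window = NULL, exercise_id = NA_integer_,
                              deviation = "range") {
  names(tracks) <- vapply(tracks, function(t) t$marker, character(1))
  missing <- setdiff(SCORING_MARKERS, names(tracks))
  if (length(missing)) {
    stop(sprintf("marker %s required", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  per_marker <- vapply(SCORING_MARKERS, function(m) {
    marker_displacement(tracks[[m]], window, deviation = deviation)
  }, numeric(1))
  l3 <- if ("L3" %in% names(tracks)) {
    marker_displacement(tracks[["L3"]], window, deviation = deviation)
  } else NA_real_
  structure(
    list(exercise_id = exercise_id, per_marker = per_marker,
         mvt = sum(per_marker), l3 = l3),
    class = "exercise_movement")
}

#' Total movement of a test
#'
#' Sums the per-exercise movements into the test total used as the raw-score
#' input. The exercise count must match the protocol: 4 for SLB (2 eyes
#' conditions x 2 legs), 4 for TBT, 6 for YBT (3 directions x 2 legs).
#'
#' @param exercises List of [exercise_movement()]s.
#' @param test_type `"SLB"`, `"TBT"` or `"YBT"`.
#' @return An object of class `test_movement` with the exercises and `total`
#'   (cm).
#' @export
test_total_movement <- function(exercises, test_type) {
  test_type <- match.arg(test_type, TEST_TYPES)
  expected <- EXERCISES_PER_TEST[[test_type]]
  if (length(exercises) != expected) {
    stop(sprintf("%s requires %d exercises, got %d",
                 test_type, expected, length(exercises)), call. = FALSE)
  }
  stopifnot(all(vapply(exercises, inherits, logical(1), "exercise_movement")))
  structure(
    list(test_type = test_type, exercises = exercises,
         total = sum(vapply(exercises, function(e) e$mvt, numeric(1)))),
    class = "test_movement")
}

#' @export
print.test_movement <- function(x, ...) {
  cat(sprintf("<test_movement> %s: %d exercises, total %.2f cm\n",
              x$test_type, length(x$exercises), x$total))
  invisible(x)
}

#' Tabulate exercise movements for export
#'
#' One row per exercise: id, per-marker displacements, mvt, and the test
#' total, matching the movement CSV contract.
#'
#' @param movement A `test_movement` object or list of them.
#' @return A `data.frame`.
#' @export
movement_table <- function(movement) {
  if (inherits(movement, "test_movement")) movement <- list(movement)
  do.call(rbind, lapply(movement, function(tm) {
    do.call(rbind, lapply(tm$exercises, function(e) {
      data.frame(test_type = tm$test_type, exercise_id = e$exercise_id,
                 acromion = e$per_marker[["acromion"]],
                 umbilicus = e$per_marker[["umbilicus"]],
                 trochanter = e$per_marker[["trochanter"]],
                 l3 = e$l3, mvt = e$mvt, test_total = tm$total,
                 stringsAsFactors = FALSE)
    }))
  }))
}
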