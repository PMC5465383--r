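# Smartphone trail making test: connect 12 circles in a prescribed order.
# Part 1: numbers ascending; part 2: letters ascending; part 3: numbers and
# letters alternating ascending (1-A-2-B); part 4: numbers ascending, letters
# descending (1-Z-2-Y), added against ceiling effects in healthy samples.

#' Target label sequence for one trail making part
#'
#' @param part integer 1-4.
#' @return Character vector of 12 symbols in tap order.
#' @export
trail_sequence <- function(part) {
  if (!is.numeric(part) || length(part) != 1L || !(part %in% 1:4)) {
    abort("`part` must be 1, 2, 3 or 4", "invalid_input")
  }
  switch(as.integer(part),
    as.character(1:12),
    LETTERS[1:12],
    as.vector(rbind(as.character(1:6), LETTERS[1:6])),
    as.vector(rbind(as.character(1:6), LETTERS[26:21]))
  )
}

#' Generate a trail making layout
#'
#' Places 12 labelled circles in the unit square by rejection sampling so that
#' no two circles come closer than `min_sep_radii` radii (always more than one
#' diameter, so circles never overlap).
#'
#' @param part integer 1-4; determines the label sequence via
#'   [trail_sequence()].
#' @param rng_seed integer seed for the positions.
#' @param layout_config list with `radius` (circle radius in layout units,
#'   default 0.05), `min_sep_radii` (minimum centre separation in radii,
#'   default 2.5) and `max_attempts` (rejection-sampling cap, default 10000).
#'
#' @return An object of class `trail_layout` with `labels` (tap order) and
#'   `positions` (12 x 2 matrix of centres).
#' @export
generate_trail_part <- function(part, rng_seed = 1L,
                                layout_config = list()) {
  cfg <- utils::modifyList(
    list(radius = 0.05, min_sep_radii = 2.5, max_attempts = 10000L),
    layout_config
  )
  labels <- trail_sequence(part)
  r <- cfg$radius
  min_d <- cfg$min_sep_radii * r
  if (r <= 0 || r >= 0.5) {
    abort("circle radius must lie in (0, 0.5) to fit the unit square",
          "layout_infeasible")
  }
  with_seed(rng_seed, {
    pos <- matrix(NA_real_, nrow = 12L, ncol = 2L,
                  dimnames = list(NULL, c("x", "y")))
    placed <- 0L
    attempts <- 0L
    while (placed < 12L) {
      attempts <- attempts + 1L
      if (attempts > cfg$max_attempts) {
        abort(sprintf(
          "could not place 12 circles of radius %g with separation %g within %d attempts",
          r, min_d, cfg$max_attempts), "layout_infeasible")
      }
      cand <- stats::runif(2L, min = r, max = 1 - r)
      if (placed == 0L ||
          all(sqrt(rowSums((pos[seq_len(placed), , drop = FALSE] -
                            matrix(cand, placed, 2, byrow = TRUE))^2)) > min_d)) {
        placed <- placed + 1L
        pos[placed, ] <- cand
      }
    }
    structure(
      list(schema_version = 1L, test_id = "tmt", part = as.integer(part),
           labels = labels, positions = pos, radius = r,
           rng_seed = as.integer(rng_seed)),
      class = "trail_layout"
    )
  })
}

#' Score a trail making tap log
#'
#' Walks the tap log against the layout's target order. The trail completes
#' only when all 12 targets have been tapped in sequence; taps on any other
#' circle count as errors and, under the default policy, do not advance the
#' trail. Completion time is the last correct tap minus the stimulus display
#' time. Duplicate taps sharing a timestamp are collapsed to the first.
#'
#' @param layout a `trail_layout`.
#' @param tap_log data frame with `time_ms` (monotone non-decreasing) and
#'   `label` (the circle tapped).
#' @param display_time_ms time at which the layout was displayed (default 0).
#' @param advance_on_error if `TRUE`, a wrong tap both counts as an error and
#'   advances past the current target (alternative policy).
#'
#' @return A [test_score()] with `time_s` and `n_errors`.
#' @export
score_trail <- function(layout, tap_log, display_time_ms = 0,
                        advance_on_error = FALSE) {
  stopifnot(inherits(layout, "trail_layout"))
  if (!all(c("time_ms", "label") %in% names(tap_log))) {
    abort("`tap_log` needs columns time_ms and label", "invalid_input")
  }
  if (is.unsorted(tap_log$time_ms)) {
    abort("tap timestamps must be monotone increasing", "invalid_input")
  }
  tap_log <- tap_log[!duplicated(tap_log$time_ms), , drop = FALSE]
  target <- 1L
  n_errors <- 0L
  finish_ms <- NA_real_
  for (i in seq_len(nrow(tap_log))) {
    if (tap_log$label[i] == layout$labels[target]) {
      if (target == 12L) {
        finish_ms <- tap_log$time_ms[i]
        break
      }
      target <- target + 1L
    } else {
      n_errors <- n_errors + 1L
      if (advance_on_error) {
        if (target == 12L) {
          finish_ms <- tap_log$time_ms[i]
          break
        }
        target <- target + 1L
      }
    }
  }
  if (is.na(finish_ms)) {
    abort("tap log ended before the 12-circle trail was completed",
          "incomplete_session")
  }
  test_score("tmt", layout$part,
             time_s = (finish_ms - display_time_ms) / 1000,
             n_errors = n_errors)
}
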