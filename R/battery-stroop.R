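# Smartphone Stroop colour-word test: three 30-item multiple-choice panels.
# Part 1: colour names printed in black; part 2: coloured blocks; part 3:
# colour names printed in a conflicting ink colour (interference panel).

#' Generate a Stroop panel
#'
#' @param part integer 1-3.
#' @param color_set character vector of at least 2 colour names; every item
#'   offers the full set as answer options.
#' @param rng_seed integer seed.
#' @param n_items items per panel (default 30).
#'
#' @return An object of class `stroop_panel` whose `items` data frame has
#'   columns `display_text`, `display_color`, `correct_answer`; part-3 items
#'   are always incongruent (`display_text != display_color`).
#' @export
generate_stroop_panel <- function(part,
                                  color_set = c("red", "green", "blue", "yellow"),
                                  rng_seed = 1L, n_items = 30L) {
  if (!is.numeric(part) || length(part) != 1L || !(part %in% 1:3)) {
    abort("`part` must be 1, 2 or 3", "invalid_input")
  }
  color_set <- unique(as.character(color_set))
  if (length(color_set) < 2L) {
    abort("`color_set` needs at least 2 colours (part 3 requires incongruence)",
          "invalid_input")
  }
  n_items <- assert_scalar_count(n_items, "n_items")
  with_seed(rng_seed, {
    named <- sample(color_set, n_items, replace = TRUE)
    items <- switch(as.integer(part),
      data.frame(display_text = named, display_color = "black",
                 correct_answer = named, stringsAsFactors = FALSE),
      data.frame(display_text = "", display_color = named,
                 correct_answer = named, stringsAsFactors = FALSE),
      {
        ink <- vapply(named, function(w) sample(setdiff(color_set, w), 1L), "")
        data.frame(display_text = named, display_color = unname(ink),
                   correct_answer = unname(ink), stringsAsFactors = FALSE)
      }
    )
    structure(
      list(schema_version = 1L, test_id = "stroop", part = as.integer(part),
           items = items, answer_options = color_set,
           rng_seed = as.integer(rng_seed)),
      class = "stroop_panel"
    )
  })
}

#' Score a Stroop panel response log
#'
#' Tallies selected options against each item's correct answer; the panel
#' completion time is the last response timestamp minus the panel display
#' time, reported in seconds.
#'
#' @param panel a `stroop_panel`.
#' @param responses data frame with one row per item: `answer` (selected
#'   option) and `time_ms`.
#' @param display_time_ms panel display time (default 0).
#'
#' @return A [test_score()] with `time_s`, `n_correct`, `n_incorrect` and a
#'   `details$below_half_correct` flag used by the mistake-filtered
#'   sensitivity analysis.
#' @export
score_stroop <- function(panel, responses, display_time_ms = 0) {
  stopifnot(inherits(panel, "stroop_panel"))
  n <- nrow(panel$items)
  if (!is.data.frame(responses) || nrow(responses) != n ||
      !all(c("answer", "time_ms") %in% names(responses)) ||
      anyNA(responses$answer)) {
    abort("one answered option per item is required", "incomplete_session")
  }
  n_correct <- sum(responses$answer == panel$items$correct_answer)
  test_score("stroop", panel$part,
             time_s = (max(responses$time_ms) - display_time_ms) / 1000,
             n_correct = n_correct, n_incorrect = n - n_correct,
             details = list(below_half_correct = n_correct < n / 2))
}
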