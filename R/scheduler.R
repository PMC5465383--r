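# Reminder calendar and adherence. Each of the five tests is actively offered
# at least four times, evenly spread over the 6-month (182-day) follow-up;
# adherence is performance of the test within one week of its reminder.

#' Default reminder day offsets
#'
#' The study calendar: day offsets since baseline on which the reminder for
#' each test was sent.
#'
#' @return Named list of integer day-offset vectors.
#' @export
default_offsets <- function() {
  list(
    memory_word = c(1L, 29L, 99L, 169L),
    tmt = c(2L, 43L, 113L, 170L),
    stroop = c(3L, 57L, 127L, 171L),
    reaction = c(4L, 71L, 141L, 172L),
    nback = c(15L, 85L, 155L, 173L)
  )
}

#' Build a reminder schedule
#'
#' @param config optional list overriding the defaults: `offsets` (named list
#'   of strictly increasing day offsets, at least 4 per test, all within the
#'   182-day follow-up), `window_days` (adherence window length, default 7)
#'   and `window_closed` (if `TRUE` the window is the closed interval
#'   `[day, day + window]`; default `FALSE`, i.e. half-open
#'   `[day, day + window)`).
#'
#' @return An object of class `reminder_schedule`.
#' @export
build_schedule <- function(config = list()) {
  cfg <- utils::modifyList(
    list(offsets = default_offsets(), window_days = 7L, window_closed = FALSE),
    config
  )
  # A user-supplied offsets list replaces the calendar wholesale: scheduling
  # only some tests must not silently retain the default reminders for others.
  if (!is.null(config$offsets)) cfg$offsets <- config$offsets
  offs <- cfg$offsets
  if (!length(offs) || is.null(names(offs)) || any(names(offs) == "")) {
    abort("`offsets` must be a named list of day-offset vectors", "invalid_config")
  }
  for (test in names(offs)) {
    d <- offs[[test]]
    if (length(d) < 4L) {
      abort(sprintf("test '%s' needs at least 4 reminders", test), "invalid_config")
    }
    if (any(diff(d) <= 0)) {
      abort(sprintf("reminder offsets for '%s' must be strictly increasing", test),
            "invalid_config")
    }
    if (any(d < 1) || any(d > 182)) {
      abort(sprintf("reminder offsets for '%s' must lie in days 1-182", test),
            "invalid_config")
    }
    offs[[test]] <- as.integer(d)
  }
  w <- assert_scalar_count(cfg$window_days, "window_days")
  structure(
    list(offsets = offs, window_days = w,
         window_closed = isTRUE(cfg$window_closed)),
    class = "reminder_schedule"
  )
}

#' @export
print.reminder_schedule <- function(x, ...) {
  cat(sprintf("<reminder_schedule> window %d days (%s)\n", x$window_days,
              if (x$window_closed) "closed" else "half-open"))
  for (t in names(x$offsets)) {
    cat(sprintf("  %-12s days %s\n", t, paste(x$offsets[[t]], collapse = ", ")))
  }
  invisible(x)
}

in_window <- function(day, reminder_day, window, closed) {
  if (closed) day >= reminder_day & day <= reminder_day + window
  else day >= reminder_day & day < reminder_day + window
}

#' Compute per-participant adherence
#'
#' A reminder is adherent when at least one completed session of its test
#' falls inside the reminder's window; a single session can satisfy at most
#' one reminder (sessions are assigned greedily to reminders in calendar
#' order). Sessions for tests absent from the schedule are ignored with a
#' warning.
#'
#' @param schedule a `reminder_schedule`.
#' @param sessions data frame with columns `participant_id`, `test_id`, `day`
#'   (days since baseline) and optionally `completed` (logical, default all
#'   `TRUE`).
#' @param participant_ids optional vector of all participant ids to report
#'   (participants with no sessions then appear with 0% adherence); defaults
#'   to the ids present in `sessions`.
#'
#' @return An object of class `adherence_result`: `by_participant` (one row
#'   per participant x test: `n_reminders`, `n_adherent`, `adherence_pct`),
#'   `by_test` (cohort mean and SD of the participant percentages per test)
#'   and `per_participant_mean` (each participant's adherent fraction pooled
#'   over all reminders of all tests) with its cohort `mean_pct`/`sd_pct`.
#' @export
compute_adherence <- function(schedule, sessions, participant_ids = NULL) {
  stopifnot(inherits(schedule, "reminder_schedule"))
  if (!all(c("participant_id", "test_id", "day") %in% names(sessions))) {
    abort("`sessions` needs participant_id, test_id and day columns",
          "invalid_input")
  }
  if (is.null(sessions$completed)) sessions$completed <- rep(TRUE, nrow(sessions))
  unknown <- setdiff(unique(sessions$test_id), names(schedule$offsets))
  if (length(unknown)) {
    warning(sprintf("ignoring sessions with unknown test_id: %s",
                    paste(unknown, collapse = ", ")))
    sessions <- sessions[sessions$test_id %in% names(schedule$offsets), ,
                         drop = FALSE]
  }
  sessions <- sessions[sessions$completed, , drop = FALSE]
  # Multi-part records of one administration collapse to a single session.
  if (!is.null(sessions$attempt_index)) {
    sessions <- sessions[!duplicated(sessions[c("participant_id", "test_id",
                                                "attempt_index")]), ,
                         drop = FALSE]
  }
  ids <- if (is.null(participant_ids)) {
    sort(unique(sessions$participant_id))
  } else {
    participant_ids
  }
  tests <- names(schedule$offsets)
  grid <- expand.grid(participant_id = ids, test_id = tests,
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid$n_reminders <- vapply(grid$test_id,
                             function(t) length(schedule$offsets[[t]]), 0L)
  grid$n_adherent <- 0L
  for (row in seq_len(nrow(grid))) {
    days <- sort(sessions$day[sessions$participant_id == grid$participant_id[row] &
                              sessions$test_id == grid$test_id[row]])
    used <- logical(length(days))
    hit <- 0L
    for (r in schedule$offsets[[grid$test_id[row]]]) {
      ok <- which(!used & in_window(days, r, schedule$window_days,
                                    schedule$window_closed))
      if (length(ok)) {
        used[ok[1L]] <- TRUE
        hit <- hit + 1L
      }
    }
    grid$n_adherent[row] <- hit
  }
  grid$adherence_pct <- 100 * grid$n_adherent / grid$n_reminders
  by_test <- do.call(rbind, lapply(tests, function(t) {
    p <- grid$adherence_pct[grid$test_id == t]
    data.frame(test_id = t, mean_pct = mean(p), sd_pct = stats::sd(p),
               stringsAsFactors = FALSE)
  }))
  per_part <- do.call(rbind, lapply(ids, function(id) {
    g <- grid[grid$participant_id == id, ]
    data.frame(participant_id = id,
               adherence_pct = 100 * sum(g$n_adherent) / sum(g$n_reminders),
               stringsAsFactors = FALSE)
  }))
  structure(
    list(by_participant = grid, by_test = by_test,
         per_participant_mean = per_part,
         mean_pct = mean(per_part$adherence_pct),
         sd_pct = stats::sd(per_part$adherence_pct)),
    class = "adherence_result"
  )
}

#' @export
print.adherence_result <- function(x, ...) {
  cat(sprintf("<adherence_result> %d participants; mean adherence %.1f%% (SD %.1f)\n",
              nrow(x$per_participant_mean), x$mean_pct, x$sd_pct))
  print(x$by_test, row.names = FALSE)
  invisible(x)
}

#' Fraction of participants who ever performed each test
#'
#' Irrespective of timing relative to any reminder.
#'
#' @param sessions session data frame (see [compute_adherence()]).
#' @param n_participants denominator (> 0).
#' @return Named numeric vector of fractions in `[0, 1]`, one per test id seen
#'   in `sessions` (0 rows gives an empty vector).
#' @export
ever_performed_fraction <- function(sessions, n_participants) {
  if (!is.numeric(n_participants) || n_participants <= 0) {
    abort("`n_participants` must be positive", "invalid_input")
  }
  if (is.null(sessions$completed)) sessions$completed <- rep(TRUE, nrow(sessions))
  sessions <- sessions[sessions$completed, , drop = FALSE]
  tests <- sort(unique(sessions$test_id))
  vapply(stats::setNames(tests, tests), function(t) {
    length(unique(sessions$participant_id[sessions$test_id == t])) / n_participants
  }, 0)
}
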