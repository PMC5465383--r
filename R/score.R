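#' Test score container
#'
#' Holds the scored outcome of one administration of one part of a smartphone
#' cognitive test: a completion time for the timed tests (trail making, Stroop),
#' correct/incorrect counts for item-based tests (word recognition, n-back,
#' Stroop), and response latencies plus a one-off startle latency for the
#' reaction-time test. Internal timing is in milliseconds; completion times are
#' reported in seconds, reaction latencies in milliseconds.
#'
#' @param test_id character id of the test (`"memory_word"`, `"tmt"`,
#'   `"stroop"`, `"reaction"`, `"nback"`).
#' @param part integer part/panel/level index within the test.
#' @param time_s completion time in seconds, `NA` for untimed tests.
#' @param n_correct,n_incorrect counts of correct and incorrect scorable
#'   responses; they must sum to the number of scorable items.
#' @param latencies_ms numeric vector of per-trial response latencies (ms).
#' @param mean_latency_ms mean of valid (non-anticipatory) latencies (ms).
#' @param startle_time_ms latency to the single enlarged startle stimulus (ms).
#' @param n_errors wrong-circle taps (trail making) or other error taps.
#' @param n_commission responses to no-go stimuli (reaction test part 2).
#' @param n_anticipatory touches recorded before the cue, excluded from means.
#' @param details free-form list of extra per-test fields.
#'
#' @return An object of class `test_score`.
#' @export
test_score <- function(test_id, part,
                       time_s = NA_real_,
                       n_correct = NA_integer_, n_incorrect = NA_integer_,
                       latencies_ms = NULL, mean_latency_ms = NA_real_,
                       startle_time_ms = NA_real_,
                       n_errors = NA_integer_, n_commission = NA_integer_,
                       n_anticipatory = NA_integer_, details = list()) {
  if (!is.na(time_s) && time_s < 0) {
    abort("completion time must be non-negative", "invalid_input")
  }
  if (!is.na(startle_time_ms) && startle_time_ms < 0) {
    abort("startle time must be non-negative", "invalid_input")
  }
  structure(
    list(
      test_id = test_id, part = as.integer(part), time_s = time_s,
      n_correct = if (is.na(n_correct)) NA_integer_ else as.integer(n_correct),
      n_incorrect = if (is.na(n_incorrect)) NA_integer_ else as.integer(n_incorrect),
      latencies_ms = latencies_ms, mean_latency_ms = mean_latency_ms,
      startle_time_ms = startle_time_ms,
      n_errors = if (is.na(n_errors)) NA_integer_ else as.integer(n_errors),
      n_commission = if (is.na(n_commission)) NA_integer_ else as.integer(n_commission),
      n_anticipatory = if (is.na(n_anticipatory)) NA_integer_ else as.integer(n_anticipatory),
      details = details
    ),
    class = "test_score"
  )
}

#' @export
print.test_score <- function(x, ...) {
  cat(sprintf("<test_score> %s part %d\n", x$test_id, x$part))
  if (!is.na(x$time_s)) cat(sprintf("  time: %.3f s\n", x$time_s))
  if (!is.na(x$n_correct)) {
    cat(sprintf("  correct/incorrect: %d/%d\n", x$n_correct, x$n_incorrect))
  }
  if (!is.na(x$mean_latency_ms)) {
    cat(sprintf("  mean latency: %.1f ms\n", x$mean_latency_ms))
  }
  if (!is.na(x$startle_time_ms)) {
    cat(sprintf("  startle: %.1f ms\n", x$startle_time_ms))
  }
  if (!is.na(x$n_errors)) cat(sprintf("  errors: %d\n", x$n_errors))
  if (!is.na(x$n_commission)) cat(sprintf("  commission errors: %d\n", x$n_commission))
  invisible(x)
}
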