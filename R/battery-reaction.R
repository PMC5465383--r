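# Reaction-time test. Part 1: a green box turns blue after a random delay and
# the participant touches the screen as fast as possible. Part 2 (go/no-go):
# the box turns blue (respond) or red (withhold); touches on red are
# commission errors. One randomly placed trial shows an enlarged blue box; the
# latency to that trial is the startle time.

#' Generate a set of reaction-time trials
#'
#' @param part integer 1 (simple) or 2 (go/no-go).
#' @param n_trials number of trials (>= 1).
#' @param rng_seed integer seed.
#' @param config list with `delay_range_s` (uniform cue-onset delay interval,
#'   default `c(1, 3)`) and `blue_fraction` (go-stimulus probability in part 2,
#'   default 0.7).
#'
#' @return An object of class `reaction_trials` whose `trials` data frame has
#'   `cue_onset_ms`, `target_type` ("blue"/"red") and `is_startle` (exactly one
#'   `TRUE`, always on a blue trial).
#' @export
generate_reaction_trials <- function(part, n_trials = 10L, rng_seed = 1L,
                                     config = list()) {
  if (!is.numeric(part) || length(part) != 1L || !(part %in% 1:2)) {
    abort("`part` must be 1 or 2", "invalid_input")
  }
  n_trials <- assert_scalar_count(n_trials, "n_trials")
  cfg <- utils::modifyList(list(delay_range_s = c(1, 3), blue_fraction = 0.7),
                           config)
  with_seed(rng_seed, {
    type <- if (part == 1L) {
      rep("blue", n_trials)
    } else {
      tt <- ifelse(stats::runif(n_trials) < cfg$blue_fraction, "blue", "red")
      if (!any(tt == "blue")) tt[sample.int(n_trials, 1L)] <- "blue"
      tt
    }
    delays <- stats::runif(n_trials, cfg$delay_range_s[1], cfg$delay_range_s[2]) * 1000
    startle <- logical(n_trials)
    blue_idx <- which(type == "blue")
    startle[blue_idx[sample.int(length(blue_idx), 1L)]] <- TRUE
    structure(
      list(schema_version = 1L, test_id = "reaction", part = as.integer(part),
           trials = data.frame(cue_onset_ms = delays, target_type = type,
                               is_startle = startle, stringsAsFactors = FALSE),
           rng_seed = as.integer(rng_seed)),
      class = "reaction_trials"
    )
  })
}

#' Score a reaction-time touch log
#'
#' Latency is touch time minus cue onset per trial, in milliseconds. Touches
#' on red (no-go) trials are commission errors; touches recorded before the
#' cue are flagged anticipatory and excluded from the latency mean. The
#' startle-trial latency is reported separately and excluded from the ordinary
#' mean.
#'
#' @param trials a `reaction_trials` object.
#' @param touch_ms numeric vector, one entry per trial: touch time in ms
#'   relative to trial start, or `NA` where the response was withheld.
#'
#' @return A [test_score()] with `latencies_ms`, `mean_latency_ms`,
#'   `startle_time_ms`, `n_commission` and `n_anticipatory`.
#' @export
score_reaction <- function(trials, touch_ms) {
  stopifnot(inherits(trials, "reaction_trials"))
  tr <- trials$trials
  if (length(touch_ms) != nrow(tr)) {
    abort("`touch_ms` must have one entry (or NA) per trial", "invalid_input")
  }
  lat <- touch_ms - tr$cue_onset_ms
  touched <- !is.na(touch_ms)
  anticipatory <- touched & lat < 0
  commission <- touched & tr$target_type == "red"
  valid_go <- touched & tr$target_type == "blue" & !anticipatory
  startle_ms <- if (any(valid_go & tr$is_startle)) {
    lat[valid_go & tr$is_startle]
  } else NA_real_
  mean_ok <- valid_go & !tr$is_startle
  test_score("reaction", trials$part,
             latencies_ms = ifelse(valid_go, lat, NA_real_),
             mean_latency_ms = if (any(mean_ok)) mean(lat[mean_ok]) else NA_real_,
             startle_time_ms = startle_ms,
             n_commission = sum(commission),
             n_anticipatory = sum(anticipatory),
             n_correct = sum(valid_go) + sum(!touched & tr$target_type == "red"),
             n_incorrect = sum(commission) + sum(anticipatory) +
               sum(!touched & tr$target_type == "blue"))
}
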