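# Relative validity: Spearman correlation between conventional baseline
# scores and smartphone scores, under three selections of the smartphone
# score: the first attempt, the mean of all attempts, and the first attempt
# with at least half of the answers correct (mistake-filtered).

#' Default pairing of conventional measures and smartphone tests
#'
#' Stroop panels pair one-to-one; the trail making "numeric" row pairs the
#' conventional part-A analogue with smartphone part 1 and the "alphanumeric"
#' row pairs part B with smartphone part 3 (the ascending alternating part).
#' The mapping is configuration, not a fixed convention.
#'
#' @return Named list; each entry has `measure` (conventional measure name),
#'   `test_id` and `part` (smartphone test).
#' @export
default_pairing <- function() {
  list(
    stroop_panel_1 = list(measure = "stroop_panel_1", test_id = "stroop", part = 1L),
    stroop_panel_2 = list(measure = "stroop_panel_2", test_id = "stroop", part = 2L),
    stroop_panel_3 = list(measure = "stroop_panel_3", test_id = "stroop", part = 3L),
    tmt_numeric = list(measure = "tmt_A", test_id = "tmt", part = 1L),
    tmt_alphanumeric = list(measure = "tmt_B", test_id = "tmt", part = 3L)
  )
}

# Per-participant smartphone score for one pairing entry under a selection
# rule: "first", "mean", or "filtered" (first attempt with at least
# `threshold` of items correct).
select_phone_score <- function(sessions, entry, selection, threshold = 0.5) {
  s <- sessions[sessions$test_id == entry$test_id & sessions$part == entry$part &
                (if (is.null(sessions$completed)) TRUE else sessions$completed), ,
                drop = FALSE]
  if (!nrow(s)) {
    return(data.frame(participant_id = character(), phone = numeric(),
                      stringsAsFactors = FALSE))
  }
  s <- s[order(s$participant_id, s$attempt_index), , drop = FALSE]
  if (selection == "filtered") {
    if (is.null(s$n_correct) || is.null(s$n_items)) {
      abort("filtered selection needs n_correct and n_items columns",
            "invalid_input")
    }
    s <- s[!is.na(s$n_correct) & !is.na(s$n_items) &
           s$n_correct >= s$n_items * threshold, , drop = FALSE]
  }
  out <- lapply(split(s, s$participant_id), function(g) {
    val <- switch(selection,
      first = g$score[1L],
      filtered = g$score[1L],
      mean = mean(g$score),
      abort(sprintf("unknown selection '%s'", selection), "invalid_input")
    )
    data.frame(participant_id = g$participant_id[1L], phone = val,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

validity_rows <- function(conventional, sessions, pairing, selection,
                          threshold = 0.5) {
  if (!all(c("participant_id", "measure", "score") %in% names(conventional))) {
    abort("`conventional` needs participant_id, measure and score columns",
          "invalid_input")
  }
  out <- lapply(names(pairing), function(label) {
    entry <- pairing[[label]]
    phone <- select_phone_score(sessions, entry, selection, threshold)
    conv <- conventional[conventional$measure == entry$measure,
                         c("participant_id", "score")]
    merged <- merge(conv, phone, by = "participant_id")
    if (nrow(merged) < 3L) {
      abort(sprintf("fewer than 3 matched pairs for '%s' (%s selection)",
                    label, selection), "insufficient_data")
    }
    r <- spearman_rho(merged$score, merged$phone)
    data.frame(label = label, measure = entry$measure,
               test_id = entry$test_id, part = entry$part,
               selection = selection, n = r$n, rho = r$rho,
               p_value = r$p_value, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Relative validity of the first smartphone attempt
#'
#' Correlates (Spearman) each participant's first attempt on the paired
#' smartphone test with their conventional baseline score.
#'
#' @param conventional long data frame `participant_id`, `measure`, `score`.
#' @param sessions session records (see [simulate_sessions()] for the layout).
#' @param pairing pairing map, see [default_pairing()].
#' @return Data frame with one row per pairing: `label`, `n`, `rho`,
#'   `p_value`.
#' @export
first_attempt_validity <- function(conventional, sessions,
                                   pairing = default_pairing()) {
  validity_rows(conventional, sessions, pairing, "first")
}

#' Relative validity of the mean over all attempts
#'
#' As [first_attempt_validity()] but the smartphone score is each
#' participant's mean across all attempts, which averages out independent
#' per-attempt measurement error.
#'
#' @inheritParams first_attempt_validity
#' @export
mean_attempt_validity <- function(conventional, sessions,
                                  pairing = default_pairing()) {
  validity_rows(conventional, sessions, pairing, "mean")
}

#' Select each participant's first attempt without many mistakes
#'
#' Returns, per participant and test part, the earliest attempt on which at
#' least `threshold` of the items were answered correctly; participants with
#' no qualifying attempt are excluded (not an error).
#'
#' @param sessions session records carrying `n_correct` and `n_items`.
#' @param threshold required fraction correct (default one half; the boundary
#'   is inclusive, 15/30 qualifies).
#' @return Subset of `sessions` rows, one per participant x test x part.
#' @export
filtered_first_valid_attempt <- function(sessions, threshold = 0.5) {
  if (is.null(sessions$n_correct) || is.null(sessions$n_items)) {
    abort("`sessions` needs n_correct and n_items columns", "invalid_input")
  }
  s <- sessions[!is.na(sessions$n_correct) & !is.na(sessions$n_items) &
                sessions$n_correct >= sessions$n_items * threshold, ,
                drop = FALSE]
  s <- s[order(s$participant_id, s$test_id, s$part, s$attempt_index), ,
         drop = FALSE]
  res <- s[!duplicated(s[c("participant_id", "test_id", "part")]), ,
           drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Relative validity of the mistake-filtered first attempt
#'
#' @inheritParams first_attempt_validity
#' @param threshold required fraction of items correct (default one half).
#' @export
filtered_attempt_validity <- function(conventional, sessions,
                                      pairing = default_pairing(),
                                      threshold = 0.5) {
  validity_rows(conventional, sessions, pairing, "filtered", threshold)
}

#' Full relative-validity report
#'
#' One row per pairing with the first-attempt, mean-of-attempts and (where
#' item counts are available) mistake-filtered Spearman correlations.
#'
#' @inheritParams filtered_attempt_validity
#' @param filtered include the mistake-filtered column (default only for
#'   pairings whose sessions carry item counts).
#' @return Data frame of class `validity_report`.
#' @export
validity_report <- function(conventional, sessions,
                            pairing = default_pairing(), threshold = 0.5,
                            filtered = TRUE) {
  first <- first_attempt_validity(conventional, sessions, pairing)
  m <- mean_attempt_validity(conventional, sessions, pairing)
  out <- data.frame(
    label = first$label, measure = first$measure, test_id = first$test_id,
    part = first$part, n = first$n,
    rho_first = first$rho, p_first = first$p_value,
    rho_mean = m$rho, p_mean = m$p_value,
    rho_filtered = NA_real_, p_filtered = NA_real_, n_filtered = NA_integer_,
    stringsAsFactors = FALSE
  )
  if (filtered) {
    for (i in seq_len(nrow(out))) {
      entry <- pairing[[out$label[i]]]
      has_counts <- any(sessions$test_id == entry$test_id &
                        sessions$part == entry$part &
                        !is.na(sessions$n_correct))
      if (!has_counts) next
      row <- tryCatch(
        validity_rows(conventional, sessions, pairing[out$label[i]],
                      "filtered", threshold),
        cogbattery_error = function(e) NULL
      )
      if (!is.null(row)) {
        out$rho_filtered[i] <- row$rho
        out$p_filtered[i] <- row$p_value
        out$n_filtered[i] <- row$n
      }
    }
  }
  class(out) <- c("validity_report", "data.frame")
  out
}
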