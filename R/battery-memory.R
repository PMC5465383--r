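# Word-list recognition memory test: study 10 words, then recognise them among
# 10 distractors (20-item yes/no recognition list).

#' Bundled default word pool
#'
#' Returns the word pool shipped with the package (common concrete nouns).
#' Any user-supplied character vector of at least 20 distinct words can be used
#' instead; the scoring is content-agnostic.
#'
#' @return Character vector of distinct lower-case words.
#' @export
default_word_pool <- function() {
  path <- system.file("extdata", "word_pool.txt", package = "cogbattery")
  readLines(path, warn = FALSE)
}

#' Generate a word-recognition memory stimulus
#'
#' Draws a 10-word study list from `word_pool` and a 20-word recognition list
#' containing those 10 studied ("old") words mixed with 10 new distractors in a
#' seeded random order.
#'
#' @param word_pool character vector of at least 20 distinct words.
#' @param rng_seed integer seed; identical seeds give identical stimuli.
#' @param presentation_pace_s seconds each study word is displayed (metadata
#'   only; the engine does not render).
#'
#' @return An object of class `word_memory_stimulus` with fields `study_list`
#'   (length 10), `recognition_list` (length 20) and `is_old` (logical, 10
#'   `TRUE`).
#' @export
generate_word_memory <- function(word_pool = default_word_pool(), rng_seed = 1L,
                                 presentation_pace_s = 2) {
  word_pool <- unique(as.character(word_pool))
  if (length(word_pool) < 20L) {
    abort("`word_pool` must contain at least 20 distinct words", "invalid_input")
  }
  with_seed(rng_seed, {
    chosen <- sample(word_pool, 20L)
    study <- chosen[1:10]
    new <- chosen[11:20]
    ord <- sample.int(20L)
    recognition <- c(study, new)[ord]
    is_old <- recognition %in% study
    structure(
      list(
        schema_version = 1L, test_id = "memory_word", part = 1L,
        study_list = study, recognition_list = recognition, is_old = is_old,
        presentation_pace_s = presentation_pace_s, rng_seed = as.integer(rng_seed)
      ),
      class = "word_memory_stimulus"
    )
  })
}

#' Score a word-recognition response vector
#'
#' A response is correct when the participant says "yes" to a studied word or
#' "no" to a new word. Correct plus incorrect always equals the 20 recognition
#' items.
#'
#' @param stimulus a `word_memory_stimulus`.
#' @param responses logical vector of length 20: `TRUE` for a "yes"
#'   (recognised) response to the corresponding recognition item. Any `NA` or a
#'   short vector is an incomplete session.
#'
#' @return A [test_score()] with `n_correct` and `n_incorrect`.
#' @export
score_word_memory <- function(stimulus, responses) {
  stopifnot(inherits(stimulus, "word_memory_stimulus"))
  responses <- as.logical(responses)
  n <- length(stimulus$recognition_list)
  if (length(responses) != n || anyNA(responses)) {
    abort("one yes/no response per recognition item is required",
          "incomplete_session")
  }
  n_correct <- sum(responses == stimulus$is_old)
  test_score("memory_word", 1L, n_correct = n_correct,
             n_incorrect = n - n_correct)
}
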