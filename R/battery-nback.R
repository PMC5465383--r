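# Letter n-back working-memory test. Levels 0-3 are presented as sequences of
# 11, 11, 15 and 20 letters. At level 0 the target letter is a fixed 'X'; at
# level n >= 1 a position is a target when its letter equals the letter n
# positions earlier. Generation plants a requested number of targets and then
# verifies the whole sequence against the n-back rule so no accidental targets
# slip in.

NBACK_LENGTHS <- c(`0` = 11L, `1` = 11L, `2` = 15L, `3` = 20L)
NBACK_DEFAULT_TARGETS <- c(`0` = 3L, `1` = 3L, `2` = 4L, `3` = 5L)

# Independent definition of the target rule; used both to verify generation
# and as the reference in tests.
nback_targets <- function(letters, n_level) {
  L <- length(letters)
  if (n_level == 0L) return(letters == "X")
  idx <- seq_len(L)
  out <- logical(L)
  keep <- idx > n_level
  out[keep] <- letters[idx[keep]] == letters[idx[keep] - n_level]
  out
}

#' Generate a letter n-back sequence
#'
#' @param n_level integer 0-3. Sequence lengths are fixed at 11, 11, 15 and 20
#'   letters for levels 0-3.
#' @param rng_seed integer seed.
#' @param target_config list with `n_targets` (planted target count; default
#'   3, 3, 4 and 5 for levels 0-3, roughly 30% of scorable positions) and
#'   `alphabet` (letters used; 'X' is reserved for level 0 targets).
#'
#' @return An object of class `nback_sequence` with `letters` and `is_target`;
#'   `is_target` provably satisfies the n-back rule (verified by a full
#'   re-scan at generation time).
#' @export
generate_nback <- function(n_level, rng_seed = 1L, target_config = list()) {
  if (!is.numeric(n_level) || length(n_level) != 1L || !(n_level %in% 0:3)) {
    abort("`n_level` must be 0, 1, 2 or 3", "invalid_input")
  }
  n_level <- as.integer(n_level)
  L <- NBACK_LENGTHS[[as.character(n_level)]]
  cfg <- utils::modifyList(
    list(n_targets = NBACK_DEFAULT_TARGETS[[as.character(n_level)]],
         alphabet = setdiff(LETTERS, "X")),
    target_config
  )
  k <- assert_scalar_count(cfg$n_targets, "n_targets", min = 0L)
  n_eligible <- L - max(n_level, 0L)
  if (n_level == 0L) n_eligible <- L
  if (k > n_eligible) {
    abort(sprintf("%d targets are infeasible for level %d (length %d)",
                  k, n_level, L), "invalid_input")
  }
  if (length(cfg$alphabet) < 2L) {
    abort("alphabet needs at least 2 letters", "invalid_input")
  }
  with_seed(rng_seed, {
    eligible <- if (n_level == 0L) seq_len(L) else (n_level + 1L):L
    target_pos <- sort(sample(eligible, k))
    letters_out <- character(L)
    for (i in seq_len(L)) {
      if (n_level == 0L) {
        letters_out[i] <- if (i %in% target_pos) "X" else sample(cfg$alphabet, 1L)
      } else if (i <= n_level) {
        letters_out[i] <- sample(cfg$alphabet, 1L)
      } else if (i %in% target_pos) {
        letters_out[i] <- letters_out[i - n_level]
      } else {
        letters_out[i] <- sample(setdiff(cfg$alphabet, letters_out[i - n_level]), 1L)
      }
    }
    is_target <- nback_targets(letters_out, n_level)
    stopifnot(identical(which(is_target), as.integer(target_pos)))
    structure(
      list(schema_version = 1L, test_id = "nback", n_level = n_level,
           part = n_level + 1L, letters = letters_out, is_target = is_target,
           rng_seed = as.integer(rng_seed)),
      class = "nback_sequence"
    )
  })
}

#' Score touches against an n-back sequence
#'
#' Hits are touches on target positions, false alarms touches on non-targets,
#' misses untouched targets; `n_correct` counts hits plus correct rejections.
#'
#' @param sequence an `nback_sequence`.
#' @param touches integer vector of touched positions (1-based), possibly
#'   empty.
#'
#' @return A [test_score()]; `details` carries `hits`, `false_alarms`,
#'   `misses` and `correct_rejections`.
#' @export
score_nback <- function(sequence, touches = integer()) {
  stopifnot(inherits(sequence, "nback_sequence"))
  touches <- unique(as.integer(touches))
  L <- length(sequence$letters)
  if (length(touches) && (any(touches < 1L) || any(touches > L))) {
    abort("touched positions must lie within the sequence", "invalid_input")
  }
  touched <- seq_len(L) %in% touches
  hits <- sum(touched & sequence$is_target)
  fa <- sum(touched & !sequence$is_target)
  misses <- sum(!touched & sequence$is_target)
  cr <- sum(!touched & !sequence$is_target)
  test_score("nback", sequence$part,
             n_correct = hits + cr, n_incorrect = fa + misses,
             details = list(hits = hits, false_alarms = fa, misses = misses,
                            correct_rejections = cr))
}
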