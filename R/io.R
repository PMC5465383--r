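# File formats: stimulus sets as single JSON documents (schema-versioned),
# session records as JSON lines (one record per line), analysis tables as CSV.

stimulus_classes <- c(
  memory_word = "word_memory_stimulus", tmt = "trail_layout",
  stroop = "stroop_panel", reaction = "reaction_trials",
  nback = "nback_sequence"
)

#' Write a stimulus set to JSON
#'
#' @param stimulus any generated stimulus object (word memory, trail layout,
#'   Stroop panel, reaction trials, n-back sequence).
#' @param path output file.
#' @export
write_stimulus_json <- function(stimulus, path) {
  if (!stimulus$test_id %in% names(stimulus_classes)) {
    abort("not a recognised stimulus object", "invalid_input")
  }
  x <- unclass(stimulus)
  if (!is.null(x$positions)) {
    x$positions <- as.data.frame(x$positions)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a stimulus set from JSON
#'
#' Inverse of [write_stimulus_json()]; restores the class from the stored
#' `test_id`.
#'
#' @param path JSON file written by [write_stimulus_json()].
#' @return The stimulus object.
#' @export
read_stimulus_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(x$test_id) || !x$test_id %in% names(stimulus_classes)) {
    abort("file does not hold a recognised stimulus set", "invalid_input")
  }
  if (!is.null(x$positions)) {
    x$positions <- as.matrix(x$positions)
  }
  structure(x, class = stimulus_classes[[x$test_id]])
}

#' Write session records as JSON lines
#'
#' One JSON object per line, append-friendly.
#'
#' @param sessions session-record data frame.
#' @param path output file.
#' @export
write_sessions_jsonl <- function(sessions, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(sessions))) {
    writeLines(jsonlite::toJSON(as.list(sessions[i, , drop = FALSE]),
                                auto_unbox = TRUE, digits = NA, na = "null"),
               con)
  }
  invisible(path)
}

#' Read session records from JSON lines
#'
#' @param path file written by [write_sessions_jsonl()].
#' @return Session-record data frame.
#' @export
read_sessions_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    x[vapply(x, is.null, logical(1))] <- NA
    as.data.frame(x, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
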