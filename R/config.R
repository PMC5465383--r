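# Study configuration: one validated list drives the whole pipeline.

default_study_config <- function() {
  list(
    rng_seed = 1L,
    n_participants = 151L,
    schedule = list(),    # overrides for build_schedule()
    population = list(),  # overrides for default_population()
    battery = list(
      word_pool_path = NULL,      # NULL -> bundled pool
      stroop_colors = c("red", "green", "blue", "yellow"),
      nback_targets = c(3L, 3L, 4L, 5L),
      reaction_n_trials = 10L
    ),
    analysis = list(
      min_attempts = 9L,
      threshold = 0.5,
      pairing = NULL              # NULL -> default_pairing()
    )
  )
}

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    abort(sprintf("unknown %s key(s): %s", where, paste(bad, collapse = ", ")),
          "config_error")
  }
}

#' Build a validated study configuration
#'
#' @param overrides nested list of overrides; unknown keys are rejected.
#' @return Validated configuration list with defaults applied (defaults
#'   reproduce the study protocol: the standard reminder calendar, a 6-month
#'   horizon and 151 participants).
#' @export
study_config <- function(overrides = list()) {
  if (is.null(overrides)) overrides <- list()
  defaults <- default_study_config()
  check_keys(overrides, names(defaults), "config")
  check_keys(overrides$schedule, c("offsets", "window_days", "window_closed"),
             "schedule")
  check_keys(overrides$population, names(default_population()), "population")
  check_keys(overrides$battery, names(defaults$battery), "battery")
  check_keys(overrides$analysis, names(defaults$analysis), "analysis")
  cfg <- utils::modifyList(defaults, overrides)
  assert_scalar_count(cfg$n_participants, "n_participants")
  build_schedule(cfg$schedule)  # validates offsets early
  cfg
}

#' Load a study configuration file
#'
#' Reads a YAML or JSON configuration, validates it against the known schema
#' (unknown keys are rejected) and applies defaults. An empty file yields the
#' full default configuration.
#'
#' @param path file path; `.json` is parsed with jsonlite, anything else with
#'   yaml.
#' @return Validated configuration list (see [study_config()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file '%s' does not exist", path), "config_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  study_config(raw)
}
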