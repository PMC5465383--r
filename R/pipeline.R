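# Umbrella pipeline: simulate -> score -> adherence -> validity -> learning
# trend, under a single seed, with a manifest enabling bit-identical reruns.

#' Run the full simulation and analysis pipeline
#'
#' Draws a cohort, simulates smartphone session logs and conventional baseline
#' scores, computes adherence and the ever-performed fractions, the
#' relative-validity report and the practice-effect report, and writes all
#' artifacts plus a manifest to `out_dir`. All randomness derives from the
#' configured seed, so two runs with the same configuration produce
#' byte-identical files.
#'
#' @param config validated configuration from [study_config()] or
#'   [load_config()].
#' @param out_dir output directory (created if missing; must be writable).
#' @param seed overrides `config$rng_seed` when given.
#'
#' @return Invisibly, a list with the in-memory results and the artifact
#'   paths.
#' @export
run_pipeline <- function(config = study_config(), out_dir, seed = NULL) {
  if (is.null(seed)) seed <- config$rng_seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, mode = 2L) != 0L) {
    abort(sprintf("output directory '%s' is not writable", out_dir), "io_error")
  }
  schedule <- build_schedule(config$schedule)
  cohort <- draw_cohort(config$n_participants, child_seed(seed, "cohort"),
                        config$population)
  sessions <- simulate_sessions(cohort, schedule, child_seed(seed, "sessions"))
  conventional <- simulate_conventional_baseline(
    cohort, child_seed(seed, "conventional"))
  message(sprintf("pipeline: %d participants, %d session records",
                  nrow(cohort), nrow(sessions)))

  adherence <- compute_adherence(schedule, sessions,
                                 participant_ids = cohort$participant_id)
  ever <- ever_performed_fraction(sessions, nrow(cohort))
  pairing <- if (is.null(config$analysis$pairing)) default_pairing() else
    config$analysis$pairing
  validity <- validity_report(conventional, sessions, pairing,
                              threshold = config$analysis$threshold)
  notes <- character()
  trend <- tryCatch(
    repeat_effect_report(sessions, config$analysis$min_attempts),
    cogbattery_error = function(e) {
      notes <<- c(notes, paste("frequent-tester subset unavailable:",
                               conditionMessage(e)))
      repeat_effect_report(sessions, 1L)
    }
  )

  paths <- list(
    sessions = file.path(out_dir, "sessions.csv"),
    sessions_jsonl = file.path(out_dir, "sessions.jsonl"),
    conventional = file.path(out_dir, "conventional.csv"),
    adherence = file.path(out_dir, "adherence_by_participant.csv"),
    adherence_summary = file.path(out_dir, "adherence_summary.json"),
    validity = file.path(out_dir, "validity.csv"),
    trend = file.path(out_dir, "trend.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  utils::write.csv(sessions, paths$sessions, row.names = FALSE)
  write_sessions_jsonl(sessions, paths$sessions_jsonl)
  utils::write.csv(conventional, paths$conventional, row.names = FALSE)
  utils::write.csv(adherence$by_participant, paths$adherence, row.names = FALSE)
  jsonlite::write_json(
    list(by_test = adherence$by_test,
         mean_pct = adherence$mean_pct, sd_pct = adherence$sd_pct,
         ever_performed = as.list(ever)),
    paths$adherence_summary, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(as.data.frame(validity), paths$validity, row.names = FALSE)
  utils::write.csv(trend, paths$trend, row.names = FALSE)

  config_path <- file.path(out_dir, "config_resolved.json")
  jsonlite::write_json(config, config_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  paths$config <- config_path
  jsonlite::write_json(
    list(package = "cogbattery",
         version = as.character(utils::packageVersion("cogbattery")),
         seed = seed,
         config_md5 = unname(tools::md5sum(config_path)),
         notes = notes),
    paths$manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(
    schedule = schedule, cohort = cohort, sessions = sessions,
    conventional = conventional, adherence = adherence, ever_performed = ever,
    validity = validity, trend = trend, paths = paths, notes = notes
  ))
}
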