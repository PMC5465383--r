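# Synthetic respondents. One latent general ability drives both the
# "conventional" baseline scores and the smartphone scores, so the rank
# correlation between instruments is controlled by the instrument noise.
# Timed smartphone scores follow
#   time = base(test, part) + between-person speed + practice_slope*(attempt-1)
#          - ability_loading*ability + lognormal per-attempt noise,
# item-based scores are binomial with an ability-linked logistic accuracy, and
# each reminder is answered with probability p_adhere_0 * decay^week until
# dropout.

#' Default population configuration for the simulator
#'
#' Defaults emulate the study conditions: a 151-person cohort followed for 6
#' months, roughly 60% and slowly declining reminder adherence, ~8% dropout,
#' practice effects on the timed tests only (about -1.8 s/attempt on the
#' reversed-alphanumeric trail part and -0.9 s/attempt on the Stroop
#' interference panel), and positively skewed completion times.
#'
#' @return A named list; pass a partially overridden copy to [draw_cohort()].
#' @export
default_population <- function() {
  list(
    ability_sd = 1,
    p_adhere_0 = 0.68,
    adherence_decay = 0.99,      # per-week multiplicative decay
    dropout_prob = 0.08,         # uniform dropout day over follow-up
    extra_session_rate = 0.5,    # Poisson mean of self-initiated sessions/test
    follow_up_days = 182L,
    attempt_noise_meanlog = log(6),  # additive lognormal per-attempt noise (s);
    attempt_noise_sdlog = 0.6,       # SD ~4.8 s, typical retest variability
    attempt_noise_scale = 1,
    practice = list(
      tmt = list(mean = -1.8, sd = 0.5),
      stroop = list(mean = -0.93, sd = 0.5)
    ),
    timed = list(
      tmt = list(base = c(20, 25, 35, 45), between_sd = 6, ability_loading = 5),
      stroop = list(base = c(30, 35, 45), between_sd = 6, ability_loading = 5)
    ),
    accuracy = list(
      memory_word = list(n_items = 20L, intercept = stats::qlogis(0.85),
                         loading = 0.7),
      nback = list(n_items = c(11L, 11L, 15L, 20L),
                   intercept = stats::qlogis(0.9), loading = 0.6,
                   part_penalty = 0.25),
      stroop = list(n_items = 30L)
    ),
    stroop_mistake_beta = c(2, 38),  # per-item mistake probability ~ Beta
    reaction = list(base_ms = 400, between_sd_ms = 40, ability_loading_ms = 25,
                    noise_sdlog = 0.12),
    conventional = list(
      stroop_panel_1 = list(base = 45, ability_loading = 6, noise_sd = 8),
      stroop_panel_2 = list(base = 60, ability_loading = 7, noise_sd = 9),
      stroop_panel_3 = list(base = 90, ability_loading = 10, noise_sd = 12),
      tmt_A = list(base = 35, ability_loading = 7, noise_sd = 9),
      tmt_B = list(base = 80, ability_loading = 12, noise_sd = 15)
    )
  )
}

#' Draw a synthetic cohort of respondent profiles
#'
#' @param n number of participants (>= 1).
#' @param rng_seed integer seed.
#' @param population_config list of overrides merged into
#'   [default_population()].
#'
#' @return A data frame of class `respondent_cohort`, one row per participant,
#'   with the latent ability, a between-person speed factor, per-test practice
#'   slopes, adherence parameters, a dropout day (`NA` for completers) and the
#'   Stroop per-item mistake rate. The effective population configuration is
#'   attached as attribute `"population"`.
#' @export
draw_cohort <- function(n, rng_seed = 1L, population_config = list()) {
  n <- assert_scalar_count(n, "n")
  pop <- utils::modifyList(default_population(), population_config)
  if (pop$p_adhere_0 < 0 || pop$p_adhere_0 > 1 ||
      pop$adherence_decay < 0 || pop$adherence_decay > 1 ||
      pop$dropout_prob < 0 || pop$dropout_prob > 1) {
    abort("adherence/dropout probabilities must lie in [0, 1]", "invalid_config")
  }
  if (pop$ability_sd < 0 || pop$attempt_noise_sdlog < 0) {
    abort("population standard deviations must be non-negative", "invalid_config")
  }
  with_seed(rng_seed, {
    drops <- stats::runif(n) < pop$dropout_prob
    cohort <- data.frame(
      participant_id = sprintf("P%03d", seq_len(n)),
      latent_ability = stats::rnorm(n, 0, pop$ability_sd),
      person_speed = stats::rnorm(n),
      practice_slope_tmt = stats::rnorm(n, pop$practice$tmt$mean,
                                        pop$practice$tmt$sd),
      practice_slope_stroop = stats::rnorm(n, pop$practice$stroop$mean,
                                           pop$practice$stroop$sd),
      p_adhere_0 = pop$p_adhere_0,
      adherence_decay = pop$adherence_decay,
      dropout_day = ifelse(drops,
                           stats::runif(n, 1, pop$follow_up_days), NA_real_),
      mistake_rate = stats::rbeta(n, pop$stroop_mistake_beta[1],
                                  pop$stroop_mistake_beta[2]),
      stringsAsFactors = FALSE
    )
    attr(cohort, "population") <- pop
    class(cohort) <- c("respondent_cohort", "data.frame")
    cohort
  })
}

# One timed-test completion time (vectorized over participants).
timed_time_s <- function(pop, test, part, ability, person_speed, slope, attempt,
                         noise) {
  t <- pop$timed[[test]]
  raw <- t$base[part] + t$between_sd * person_speed -
    t$ability_loading * ability + slope * (attempt - 1) + noise
  pmax(raw, 0.5)
}

attempt_noise <- function(pop, n) {
  pop$attempt_noise_scale *
    stats::rlnorm(n, pop$attempt_noise_meanlog, pop$attempt_noise_sdlog)
}

#' Simulate smartphone session logs for a cohort
#'
#' For every reminder in `schedule` the participant responds with probability
#' `p_adhere_0 * decay^week` (week of the reminder), performs the test on a
#' uniformly chosen day inside the adherence window, and only while still
#' enrolled (before `dropout_day`). Self-initiated extra sessions arrive at a
#' configurable Poisson rate per test. Scores follow the population model
#' described above; `attempt_index` counts a participant's completed sessions
#' of a test in day order.
#'
#' @param cohort a `respondent_cohort` from [draw_cohort()].
#' @param schedule a `reminder_schedule` from [build_schedule()].
#' @param rng_seed integer seed.
#'
#' @return A long data frame of session records: `participant_id`, `test_id`,
#'   `part`, `attempt_index`, `day`, `score`, `n_correct`, `n_items`,
#'   `completed`. `score` is the completion time in seconds for the trail
#'   making and Stroop tests, the number correct for the word-recognition and
#'   n-back tests, and the mean response latency in ms for the reaction test.
#' @export
simulate_sessions <- function(cohort, schedule = build_schedule(), rng_seed = 1L) {
  stopifnot(inherits(cohort, "respondent_cohort"),
            inherits(schedule, "reminder_schedule"))
  pop <- attr(cohort, "population")
  tests <- names(schedule$offsets)
  with_seed(rng_seed, {
    out <- vector("list", nrow(cohort) * length(tests))
    k <- 0L
    for (i in seq_len(nrow(cohort))) {
      prof <- cohort[i, ]
      horizon <- if (is.na(prof$dropout_day)) pop$follow_up_days else prof$dropout_day
      for (test in tests) {
        reminders <- schedule$offsets[[test]]
        week <- floor(reminders / 7)
        p <- prof$p_adhere_0 * prof$adherence_decay^week
        responded <- stats::runif(length(reminders)) < p
        days <- reminders + sample.int(schedule$window_days, length(reminders),
                                       replace = TRUE) - 1L
        days <- days[responded & days < horizon]
        n_extra <- stats::rpois(1L, pop$extra_session_rate)
        if (n_extra > 0L) {
          extra <- stats::runif(n_extra, 1, pop$follow_up_days)
          days <- c(days, extra[extra < horizon])
        }
        days <- sort(days)
        if (!length(days)) next
        k <- k + 1L
        out[[k]] <- simulate_test_scores(pop, prof, test, days)
      }
    }
    res <- if (k) do.call(rbind, out[seq_len(k)]) else
      data.frame(participant_id = character(), test_id = character(),
                 part = integer(), attempt_index = integer(), day = numeric(),
                 score = numeric(), n_correct = integer(), n_items = integer(),
                 completed = logical(), stringsAsFactors = FALSE)
    rownames(res) <- NULL
    res
  })
}

# Rows for all parts of all attempts of one test for one participant.
# Consumes RNG; callers must hold the seed.
simulate_test_scores <- function(pop, prof, test, days) {
  attempts <- seq_along(days)
  rows <- list()
  if (test %in% c("tmt", "stroop")) {
    n_parts <- length(pop$timed[[test]]$base)
    slope <- prof[[paste0("practice_slope_", test)]]
    for (p in seq_len(n_parts)) {
      time_s <- timed_time_s(pop, test, p, prof$latent_ability,
                             prof$person_speed, slope, attempts,
                             attempt_noise(pop, length(attempts)))
      n_items <- if (test == "stroop") pop$accuracy$stroop$n_items else NA_integer_
      n_correct <- if (test == "stroop") {
        stats::rbinom(length(attempts), n_items, 1 - prof$mistake_rate)
      } else NA_integer_
      rows[[p]] <- data.frame(
        participant_id = prof$participant_id, test_id = test, part = p,
        attempt_index = attempts, day = days, score = time_s,
        n_correct = n_correct, n_items = n_items, completed = TRUE,
        stringsAsFactors = FALSE
      )
    }
  } else if (test == "memory_word") {
    acc <- pop$accuracy$memory_word
    pr <- stats::plogis(acc$intercept + acc$loading * prof$latent_ability)
    nc <- stats::rbinom(length(attempts), acc$n_items, pr)
    rows[[1]] <- data.frame(
      participant_id = prof$participant_id, test_id = test, part = 1L,
      attempt_index = attempts, day = days, score = nc,
      n_correct = nc, n_items = acc$n_items, completed = TRUE,
      stringsAsFactors = FALSE
    )
  } else if (test == "nback") {
    acc <- pop$accuracy$nback
    for (p in 1:4) {
      pr <- stats::plogis(acc$intercept + acc$loading * prof$latent_ability -
                          acc$part_penalty * (p - 1))
      nc <- stats::rbinom(length(attempts), acc$n_items[p], pr)
      rows[[p]] <- data.frame(
        participant_id = prof$participant_id, test_id = test, part = p,
        attempt_index = attempts, day = days, score = nc,
        n_correct = nc, n_items = acc$n_items[p], completed = TRUE,
        stringsAsFactors = FALSE
      )
    }
  } else if (test == "reaction") {
    rx <- pop$reaction
    for (p in 1:2) {
      mu <- rx$base_ms + rx$between_sd_ms * prof$person_speed -
        rx$ability_loading_ms * prof$latent_ability
      lat <- pmax(mu, 100) * exp(stats::rnorm(length(attempts), 0, rx$noise_sdlog))
      rows[[p]] <- data.frame(
        participant_id = prof$participant_id, test_id = test, part = p,
        attempt_index = attempts, day = days, score = lat,
        n_correct = NA_integer_, n_items = NA_integer_, completed = TRUE,
        stringsAsFactors = FALSE
      )
    }
  } else {
    abort(sprintf("no score model for test '%s'", test), "invalid_config")
  }
  do.call(rbind, rows)
}

#' Simulate conventional baseline test scores
#'
#' Conventional scores are a decreasing function of the same latent ability
#' that drives the smartphone scores, plus independent Gaussian instrument
#' noise, so the induced smartphone/conventional rank correlation is
#' controlled by the noise SDs.
#'
#' @param cohort a `respondent_cohort`.
#' @param rng_seed integer seed.
#' @param noise_config optional overrides: either a single `noise_sd` applied
#'   to every measure, or per-measure lists merged into the population's
#'   `conventional` block.
#'
#' @return Long data frame `participant_id`, `measure`, `score` for the five
#'   conventional measures (Stroop panels 1-3, trail making A and B).
#' @export
simulate_conventional_baseline <- function(cohort, rng_seed = 1L,
                                           noise_config = list()) {
  stopifnot(inherits(cohort, "respondent_cohort"))
  if (!nrow(cohort)) abort("`cohort` must be nonempty", "invalid_input")
  pop <- attr(cohort, "population")
  conv <- pop$conventional
  if (!is.null(noise_config$noise_sd)) {
    conv <- lapply(conv, function(m) { m$noise_sd <- noise_config$noise_sd; m })
  } else {
    conv <- utils::modifyList(conv, noise_config)
  }
  with_seed(rng_seed, {
    do.call(rbind, lapply(names(conv), function(m) {
      cfg <- conv[[m]]
      data.frame(
        participant_id = cohort$participant_id, measure = m,
        score = cfg$base - cfg$ability_loading * cohort$latent_ability +
          stats::rnorm(nrow(cohort), 0, cfg$noise_sd),
        stringsAsFactors = FALSE
      )
    }))
  })
}

#' Population Spearman correlation implied by a configuration
#'
#' Estimates, by a large Monte-Carlo sample, the population Spearman
#' correlation between a conventional measure and the first smartphone attempt
#' of a timed test under a given population configuration.
#'
#' @param population population configuration list (see
#'   [default_population()]).
#' @param test,part smartphone timed test and part.
#' @param measure conventional measure name.
#' @param conv_noise_sd conventional-instrument noise SD override (`NULL`
#'   keeps the configured value).
#' @param n Monte-Carlo sample size.
#' @param rng_seed integer seed.
#' @return Scalar Spearman correlation estimate.
#' @export
population_spearman <- function(population = default_population(),
                                test = "stroop", part = 3,
                                measure = "stroop_panel_3",
                                conv_noise_sd = NULL, n = 200000L,
                                rng_seed = 1L) {
  pop <- population
  cfg <- pop$conventional[[measure]]
  if (is.null(cfg)) abort(sprintf("unknown measure '%s'", measure), "invalid_config")
  if (!is.null(conv_noise_sd)) cfg$noise_sd <- conv_noise_sd
  with_seed(rng_seed, {
    ability <- stats::rnorm(n, 0, pop$ability_sd)
    speed <- stats::rnorm(n)
    slope <- stats::rnorm(n, pop$practice[[test]]$mean, pop$practice[[test]]$sd)
    phone <- timed_time_s(pop, test, part, ability, speed, slope, 1,
                          attempt_noise(pop, n))
    conv <- cfg$base - cfg$ability_loading * ability +
      stats::rnorm(n, 0, cfg$noise_sd)
    stats::cor(rank(phone), rank(conv))
  })
}

#' Calibrate conventional-instrument noise to a target rank correlation
#'
#' Solves for the conventional noise SD under which the population Spearman
#' correlation between the conventional measure and the first smartphone
#' attempt equals `target_rho`, by root finding on the Monte-Carlo estimate of
#' [population_spearman()] (common random numbers across evaluations).
#'
#' @inheritParams population_spearman
#' @param target_rho target population Spearman correlation in (0, 1).
#' @param interval search interval for the noise SD.
#' @return The calibrated noise SD.
#' @export
calibrate_conventional_noise <- function(target_rho,
                                         population = default_population(),
                                         test = "stroop", part = 3,
                                         measure = "stroop_panel_3",
                                         n = 200000L, rng_seed = 1L,
                                         interval = c(1e-3, 200)) {
  if (target_rho <= 0 || target_rho >= 1) {
    abort("`target_rho` must lie in (0, 1)", "invalid_input")
  }
  f <- function(sd) {
    population_spearman(population, test, part, measure, conv_noise_sd = sd,
                        n = n, rng_seed = rng_seed) - target_rho
  }
  if (f(interval[1]) < 0) {
    abort("even noiseless conventional scores fall below `target_rho`; reduce smartphone noise",
          "invalid_config")
  }
  stats::uniroot(f, interval = interval, tol = 1e-3)$root
}
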