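# Practice (learning) effect: linear trend in score with attempt, fitted as a
# two-level linear mixed model with a random intercept and random slope for
# attempt within participant,
#   score_ij = (b0 + u0_i) + (b1 + u1_i) * (attempt_ij - 1) + e_ij,
# estimated by REML with an unstructured 2x2 random-effects covariance.
# The attempt index is centred at the first attempt so the fixed intercept is
# first-attempt performance.

#' Fit the random-intercept/random-slope learning-trend model
#'
#' @param long_data data frame with columns `participant_id`, `attempt_index`
#'   (1-based) and `score`.
#' @param ml if `TRUE` fit by maximum likelihood instead of REML.
#' @param random_slope if `FALSE` drop the random effects entirely and fit
#'   ordinary least squares (the model with both random-effect variances
#'   constrained to zero).
#'
#' @return Object of class `trend_fit` with the fixed intercept and slope
#'   (score units per attempt), the slope standard error and p-value
#'   (Satterthwaite degrees of freedom), the random-effect variances and
#'   intercept-slope covariance, the residual variance, and convergence
#'   diagnostics.
#' @export
fit_learning_trend <- function(long_data, ml = FALSE, random_slope = TRUE) {
  need <- c("participant_id", "attempt_index", "score")
  if (!all(need %in% names(long_data))) {
    abort("`long_data` needs participant_id, attempt_index and score columns",
          "invalid_input")
  }
  d <- long_data[stats::complete.cases(long_data[need]), need]
  if (nrow(d) < 3L) abort("too few observations", "insufficient_data")
  d$attempt_c <- d$attempt_index - 1
  n_per <- table(d$participant_id)
  if (random_slope && all(n_per < 2L)) {
    abort("every participant has a single attempt; random slopes are unidentifiable",
          "degenerate_design")
  }
  if (!random_slope) {
    fit <- stats::lm(score ~ attempt_c, data = d)
    sm <- summary(fit)$coefficients
    return(structure(
      list(intercept = sm[1, 1], slope = sm[2, 1], slope_se = sm[2, 2],
           slope_p = sm[2, 4],
           var_intercept = 0, var_slope = 0, cov_intercept_slope = 0,
           var_residual = summary(fit)$sigma^2,
           n_participants = length(n_per), n_obs = nrow(d),
           reml = FALSE, random_slope = FALSE, converged = TRUE,
           messages = character()),
      class = "trend_fit"
    ))
  }
  msgs <- character()
  fit <- withCallingHandlers(
    tryCatch(
      lmerTest::lmer(score ~ attempt_c + (1 + attempt_c | participant_id),
                     data = d, REML = !ml),
      error = function(e) {
        abort(sprintf("mixed-model fit failed: %s", conditionMessage(e)),
              "fit_failure")
      }
    ),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  sm <- stats::coef(summary(fit))
  vc <- lme4::VarCorr(fit)
  vmat <- vc$participant_id
  structure(
    list(
      intercept = sm["(Intercept)", "Estimate"],
      slope = sm["attempt_c", "Estimate"],
      slope_se = sm["attempt_c", "Std. Error"],
      slope_p = sm["attempt_c", "Pr(>|t|)"],
      var_intercept = vmat[1, 1], var_slope = vmat[2, 2],
      cov_intercept_slope = vmat[1, 2],
      var_residual = attr(vc, "sc")^2,
      n_participants = length(n_per), n_obs = nrow(d),
      reml = !ml, random_slope = TRUE,
      converged = length(fit@optinfo$conv$lme4) == 0L,
      messages = msgs
    ),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %s%s; %d participants, %d observations\n",
              if (x$random_slope) "random intercept + slope" else "OLS",
              if (x$random_slope) paste0(" (", if (x$reml) "REML" else "ML", ")") else "",
              x$n_participants, x$n_obs))
  cat(sprintf("  intercept (first attempt): %.3f\n", x$intercept))
  cat(sprintf("  slope per attempt: %.3f (SE %.3f, p = %.3g)\n",
              x$slope, x$slope_se, x$slope_p))
  cat(sprintf("  variances: intercept %.3f, slope %.3f, residual %.3f\n",
              x$var_intercept, x$var_slope, x$var_residual))
  if (!x$converged) cat("  NOTE: convergence warnings; see $messages\n")
  invisible(x)
}

#' Practice-effect report across tests, with a frequent-tester subset
#'
#' Fits the learning-trend model per test part on all participants and again
#' on the subset who completed at least `min_attempts` attempts of that test
#' (default 9), probing whether selective dropout of infrequent testers
#' changes the estimated practice effect.
#'
#' @param sessions session records (long format with `score`).
#' @param min_attempts subset threshold (>= 1; 1 reproduces the unfiltered
#'   fit).
#' @param tests test ids to analyse (default: trail making and Stroop, the
#'   timed tests).
#'
#' @return Data frame with one row per test x part x subset: fitted fixed
#'   intercept/slope, slope SE and p, variance components and sample sizes.
#' @export
repeat_effect_report <- function(sessions, min_attempts = 9L,
                                 tests = c("tmt", "stroop")) {
  assert_scalar_count(min_attempts, "min_attempts")
  tests <- intersect(tests, unique(sessions$test_id))
  if (!length(tests)) abort("no matching tests in `sessions`", "insufficient_data")
  rows <- list()
  for (test in tests) {
    st <- sessions[sessions$test_id == test, , drop = FALSE]
    max_att <- tapply(st$attempt_index, st$participant_id, max)
    frequent <- names(max_att)[max_att >= min_attempts]
    for (p in sort(unique(st$part))) {
      sp <- st[st$part == p, , drop = FALSE]
      for (subset in c("all", "frequent")) {
        dd <- if (subset == "all") sp else
          sp[sp$participant_id %in% frequent, , drop = FALSE]
        if (subset == "frequent" && !length(frequent)) {
          abort(sprintf(
            "no participant reached %d attempts of '%s'", min_attempts, test),
            "insufficient_data")
        }
        # unidentifiable cells (too few observations for the random effects)
        # are reported as NA rather than aborting the whole report
        fit <- tryCatch(fit_learning_trend(dd), fit_failure = function(e) NULL)
        if (is.null(fit)) {
          fit <- list(n_participants = length(unique(dd$participant_id)),
                      n_obs = nrow(dd), intercept = NA_real_, slope = NA_real_,
                      slope_se = NA_real_, slope_p = NA_real_,
                      var_intercept = NA_real_, var_slope = NA_real_,
                      var_residual = NA_real_, converged = FALSE)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          test_id = test, part = p, subset = subset,
          min_attempts = if (subset == "frequent") min_attempts else 1L,
          n_participants = fit$n_participants, n_obs = fit$n_obs,
          intercept = fit$intercept, slope = fit$slope,
          slope_se = fit$slope_se, slope_p = fit$slope_p,
          var_intercept = fit$var_intercept, var_slope = fit$var_slope,
          var_residual = fit$var_residual, converged = fit$converged,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
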