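# Rank correlation and agreement statistics used for relative validity.

#' Spearman rank correlation with mid-rank tie handling
#'
#' Computes Spearman's rho as the Pearson correlation of mid-ranks (average
#' ranks for ties). The p-value uses the large-sample t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom; for
#' `n <= 10` without ties an exact permutation p-value is available.
#'
#' @param x,y numeric vectors of equal length; pairs with a missing member are
#'   dropped pairwise.
#' @param exact if `TRUE` and `n <= 10` with no ties, compute the exact
#'   permutation p-value (falls back to the t approximation with a warning
#'   otherwise).
#'
#' @return List with `rho`, `p_value`, `n` and `method`.
#' @export
spearman_rho <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length", "invalid_input")
  }
  keep <- !(is.na(x) | is.na(y))
  x <- as.numeric(x[keep])
  y <- as.numeric(y[keep])
  n <- length(x)
  if (n < 3L) abort("need at least 3 complete pairs", "insufficient_data")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    abort("correlation undefined: a vector is constant", "undefined_correlation")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  has_ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (exact && n <= 10L && !has_ties) {
    p <- stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
    method <- "exact permutation"
  } else {
    if (exact) {
      warning("exact p-value unavailable (ties or n > 10); using t approximation")
    }
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "t approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

#' Bland-Altman agreement of z-scored instrument pairs
#'
#' Both instruments are standardized to mean 0, SD 1 over the matched pairs,
#' placing them on a common scale; the report holds per-pair differences
#' against per-pair means, the mean difference (0 by construction of the
#' z-scoring), the SD of differences and the limits of agreement
#' (mean difference +/- 1.96 SD).
#'
#' @param conventional,smartphone numeric vectors of matched scores; pairs
#'   with a missing member are dropped.
#'
#' @return Object of class `agreement_report` with elements `data` (columns
#'   `z_conventional`, `z_smartphone`, `mean_z`, `diff_z`), `mean_diff`,
#'   `sd_diff`, `loa` (lower, upper) and `n`.
#' @export
bland_altman <- function(conventional, smartphone) {
  if (length(conventional) != length(smartphone)) {
    abort("score vectors must have equal length", "invalid_input")
  }
  keep <- !(is.na(conventional) | is.na(smartphone))
  a <- as.numeric(conventional[keep])
  b <- as.numeric(smartphone[keep])
  if (length(a) < 3L) abort("need at least 3 matched pairs", "insufficient_data")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    abort("cannot standardize a zero-variance score vector",
          "undefined_standardization")
  }
  za <- as.numeric(scale(a))
  zb <- as.numeric(scale(b))
  d <- za - zb
  m <- (za + zb) / 2
  sd_d <- stats::sd(d)
  structure(
    list(
      data = data.frame(z_conventional = za, z_smartphone = zb,
                        mean_z = m, diff_z = d),
      mean_diff = mean(d), sd_diff = sd_d,
      loa = c(lower = mean(d) - 1.96 * sd_d, upper = mean(d) + 1.96 * sd_d),
      n = length(a)
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d pairs (z-scored)\n", x$n))
  cat(sprintf("  mean difference %.4f, SD %.4f, limits of agreement [%.3f, %.3f]\n",
              x$mean_diff, x$sd_diff, x$loa[1], x$loa[2]))
  invisible(x)
}

#' Plot a Bland-Altman agreement report
#'
#' @param x an `agreement_report`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.agreement_report <- function(x, ...) {
  graphics::plot(x$data$mean_z, x$data$diff_z,
                 xlab = "Mean of z-scores", ylab = "Difference of z-scores",
                 ...)
  graphics::abline(h = c(x$mean_diff, x$loa), lty = c(1, 2, 2))
  invisible(x)
}
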