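# Independent reference implementations used to cross-check the package.
# These deliberately use naive algorithms distinct from the code under test.

# O(n^2) mid-rank computation: rank of x_i = (# strictly smaller) + half of
# (# ties including self + 1).
oracle_midranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    smaller <- 0L
    ties <- 0L
    for (j in seq_len(n)) {
      if (x[j] < x[i]) smaller <- smaller + 1L
      if (x[j] == x[i]) ties <- ties + 1L
    }
    r[i] <- smaller + (ties + 1) / 2
  }
  r
}

# Spearman rho from first principles: Pearson formula on oracle mid-ranks.
oracle_spearman <- function(x, y) {
  rx <- oracle_midranks(x)
  ry <- oracle_midranks(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Position-by-position n-back target scan.
oracle_nback_targets <- function(letters, n_level) {
  out <- logical(length(letters))
  for (i in seq_along(letters)) {
    if (n_level == 0) {
      out[i] <- letters[i] == "X"
    } else if (i > n_level) {
      out[i] <- letters[i] == letters[i - n_level]
    }
  }
  out
}

# A clean tap log that completes a trail at 1 s per circle.
clean_trail_taps <- function(layout, step_ms = 1000) {
  data.frame(time_ms = seq_along(layout$labels) * step_ms,
             label = layout$labels, stringsAsFactors = FALSE)
}
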