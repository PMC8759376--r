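# Independent oracles used across the suite.

# Two-way crossed sums of squares by explicit cell enumeration (no matrix
# shortcuts): the brute-force check for the closed-form mean squares.
brute_force_mean_squares <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  grand <- sum(m) / (n * k)
  ss_rows <- 0
  ss_cols <- 0
  ss_err <- 0
  for (i in seq_len(n)) {
    ri <- sum(m[i, ]) / k
    ss_rows <- ss_rows + k * (ri - grand)^2
  }
  for (j in seq_len(k)) {
    cj <- sum(m[, j]) / n
    ss_cols <- ss_cols + n * (cj - grand)^2
  }
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      ri <- sum(m[i, ]) / k
      cj <- sum(m[, j]) / n
      ss_err <- ss_err + (m[i, j] - ri - cj + grand)^2
    }
  }
  list(
    ms_rows = ss_rows / (n - 1),
    ms_cols = ss_cols / (k - 1),
    ms_error = ss_err / ((n - 1) * (k - 1))
  )
}

# Deterministic two-point observer: reports "two" iff the separation is at
# least the true threshold.
deterministic_observer <- function(threshold) {
  force(threshold)
  function(d) if (d >= threshold) "two" else "one"
}

# One-row score tibble in the score_session() shape, built from summary
# values (used to exercise overall_scores() against published-table inputs).
score_row <- function(test, n_trials, accuracy_pct, mean_rt_ms) {
  tibble::tibble(
    test = test,
    n_trials = n_trials,
    n_correct = round(n_trials * accuracy_pct / 100),
    accuracy_pct = accuracy_pct,
    mean_rt_ms = mean_rt_ms,
    total_rt_ms = n_trials * mean_rt_ms,
    rate_correct_per_min =
      round(n_trials * accuracy_pct / 100) / (n_trials * mean_rt_ms / 60000)
  )
}

# Serial-mediation generator with configurable true paths.
make_mediation_data <- function(n, a1 = 0, a2 = 0, d21 = 0,
                                b1 = 0, b2 = 0, c_direct = 0) {
  x <- stats::rnorm(n)
  m1 <- a1 * x + stats::rnorm(n)
  m2 <- a2 * x + d21 * m1 + stats::rnorm(n)
  y <- c_direct * x + b1 * m1 + b2 * m2 + stats::rnorm(n)
  tibble::tibble(x = x, m1 = m1, m2 = m2, y = y)
}
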