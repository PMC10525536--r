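# Independent brute-force oracles; deliberately naive, per-point loops and
# textbook formulas, never sharing code with the implementation.

# two-phase blank correction, one point at a time
oracle_correct <- function(sample, blank_mean) {
  peak_idx <- 1
  for (i in seq_along(blank_mean)) {
    if (blank_mean[i] > blank_mean[peak_idx]) peak_idx <- i
  }
  out <- numeric(length(sample))
  for (i in seq_along(sample)) {
    out[i] <- if (i <= peak_idx) sample[i] - blank_mean[i] else sample[i] - blank_mean[peak_idx]
  }
  out
}

# maximum interval slope and its earliest left endpoint, plain loop
oracle_vmax_tmax <- function(t_h, v) {
  best <- -Inf
  best_t <- NA_real_
  for (i in seq_len(length(v) - 1)) {
    slope <- (v[i + 1] - v[i]) / (t_h[i + 1] - t_h[i])
    if (slope > best) {
      best <- slope
      best_t <- t_h[i]
    }
  }
  list(vmax = best, tmax_h = best_t)
}

# two-pass unbiased SD
oracle_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# textbook Welch statistic with Welch-Satterthwaite df
oracle_welch <- function(a, b) {
  va <- oracle_sd(a)^2 / length(a)
  vb <- oracle_sd(b)^2 / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# coefficient of determination of y ~ x from explicit OLS sums
oracle_r2 <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  1 - sum((y - (a + b * x))^2) / sum((y - mean(y))^2)
}

# convenience: a gas curve from values on a 10-min grid given in hours
make_curve <- function(values, interval_min = 10, bottle_id = "b1",
                       trial_id = "t1") {
  gas_curve(seq(0, by = interval_min, length.out = length(values)), values,
            bottle_id = bottle_id, trial_id = trial_id)
}
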