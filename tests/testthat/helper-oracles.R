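# Definitional brute-force oracles, kept independent of the package's
# implementations: explicit loops and textbook formulas only.

oracle_weighted_kappa <- function(m) {
  k <- nrow(m)
  n <- sum(m)
  obs_dis <- 0
  exp_dis <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      w <- abs(i - j) / (k - 1)
      obs_dis <- obs_dis + w * m[i, j] / n
      exp_dis <- exp_dis + w * (sum(m[i, ]) / n) * (sum(m[, j]) / n)
    }
  }
  1 - obs_dis / exp_dis
}

oracle_midrank <- function(v) {
  sapply(v, function(vi) 1 + sum(v < vi) + (sum(v == vi) - 1) / 2)
}

oracle_spearman_r <- function(x, y) {
  rx <- oracle_midrank(x)
  ry <- oracle_midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

oracle_mann_whitney_u <- function(x, y) {
  u <- 0
  for (xi in x) {
    for (yj in y) {
      u <- u + (xi > yj) + 0.5 * (xi == yj)
    }
  }
  u
}

oracle_icc31 <- function(x, y) {
  dat <- cbind(x, y)
  n <- nrow(dat)
  k <- 2
  grand <- mean(dat)
  ss_rows <- 0
  for (i in seq_len(n)) ss_rows <- ss_rows + k * (mean(dat[i, ]) - grand)^2
  ss_cols <- 0
  for (j in seq_len(k)) ss_cols <- ss_cols + n * (mean(dat[, j]) - grand)^2
  ss_tot <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    ss_tot <- ss_tot + (dat[i, j] - grand)^2
  }
  ms_r <- ss_rows / (n - 1)
  ms_e <- (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  unname((ms_r - ms_e) / (ms_r + (k - 1) * ms_e))
}

# small response helper: set a few item frequencies on a blank sheet
responses_with <- function(spec, freq, respondent_id = "r1",
                           administration = "FFQ1") {
  resp <- blank_responses(spec, respondent_id, administration)
  for (item in names(freq)) {
    resp$servings_per_period[resp$item_id == item] <- freq[[item]]
  }
  resp
}
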