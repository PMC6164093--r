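make_pairs <- function(x, y) tibble::tibble(
  respondent_id = sprintf("r%03d", seq_along(x)), x = x, y = y)

test_that("Bland-Altman degenerates cleanly when methods agree exactly", {
  x <- c(1.2, 3.4, 2.2, 5.1, 0.7, 2.9)
  ba <- bland_altman(make_pairs(x, x), scale = "natural")
  expect_equal(ba$mean_difference, 0)
  expect_equal(ba$ba_index_pct, 0)  # inclusive membership at zero-width LoA
  expect_equal(ba$n_within, 6)
  ba_log <- bland_altman(make_pairs(x, x), scale = "log")
  expect_equal(ba_log$ba_index_pct, 0)
})

test_that("Bland-Altman computes limits as mean +/- 1.96 sd", {
  x <- c(2, 4, 3, 6, 5, 8, 7, 2.5)
  y <- c(1.5, 4.2, 2.2, 6.9, 4.1, 8.4, 6.2, 3.0)
  ba <- bland_altman(make_pairs(x, y), scale = "natural")
  d <- x - y
  expect_equal(ba$mean_difference, mean(d))
  expect_equal(ba$loa_lower, mean(d) - 1.96 * sd(d))
  expect_equal(ba$loa_upper, mean(d) + 1.96 * sd(d))
  ba_log <- bland_altman(make_pairs(x, y), scale = "log")
  expect_equal(ba_log$mean_difference, mean(log(x) - log(y)))
})

test_that("log-scale Bland-Altman rejects nonpositive intakes by name", {
  pairs <- make_pairs(c(1, 2, 0, 3), c(1, 2, 1, 3))
  expect_error(bland_altman(pairs, scale = "log"), "r003")
  expect_silent(bland_altman(pairs, scale = "natural"))
})

test_that("quartile cross-classification handles identity and reversal", {
  x <- c(1.1, 2.3, 3.1, 4.7, 5.2, 6.9, 7.4, 8.8, 9.1, 10.5, 11.2, 12.8)
  same <- quartile_crossclass(make_pairs(x, x))
  expect_equal(same$correct_pct, 100)
  expect_equal(same$gross_pct, 0)
  expect_equal(same$weighted_kappa, 1)

  rev <- quartile_crossclass(make_pairs(x, rev(x)))
  expect_equal(rev$correct_pct, 0)
  expect_lt(rev$weighted_kappa, 0)

  expect_error(quartile_crossclass(make_pairs(x[1:7], x[1:7])), "at least 8")
})

test_that("quartile cross-classification is respondent-order invariant", {
  withr::local_seed(11)
  x <- rlnorm(40)
  y <- x * exp(rnorm(40, sd = 0.4))
  a <- quartile_crossclass(make_pairs(x, y))
  perm <- sample(40)
  b <- quartile_crossclass(make_pairs(x[perm], y[perm]))
  expect_equal(a$matrix, b$matrix)
  expect_equal(glance(a), glance(b))
})

test_that("heavy ties leave a recorded warning, not an error", {
  x <- c(rep(1, 9), 2)
  y <- seq_len(10)
  res <- quartile_crossclass(make_pairs(x, y))
  expect_match(res$warnings, "empty quartile")
})

test_that("weighted kappa matches hand-computed and boundary cases", {
  expect_equal(weighted_kappa(diag(c(5, 7, 3, 9))), 1)
  # 2x2: linear weights reduce to unweighted Cohen's kappa
  # po = 35/50, pe = (25*30 + 25*20)/50^2 = 0.5 -> kappa = 0.4
  expect_equal(weighted_kappa(matrix(c(20, 10, 5, 15), 2, 2)), 0.4)
  # independence: cells equal to marginal products
  p <- c(0.1, 0.2, 0.3, 0.4)
  q <- c(0.25, 0.25, 0.3, 0.2)
  expect_equal(weighted_kappa(outer(p, q) * 1000), 0, tolerance = 1e-12)
  # transposition symmetry and upper bound
  withr::local_seed(3)
  for (i in 1:20) {
    m <- matrix(sample(0:9, 16, replace = TRUE) + 1, 4, 4)
    expect_equal(weighted_kappa(m), weighted_kappa(t(m)))
    expect_lte(weighted_kappa(m), 1)
  }
  # degenerate marginals: defined as 1 when nothing disagrees
  all_one_cell <- matrix(c(10, 0, 0, 0), 2, 2)
  expect_equal(weighted_kappa(all_one_cell), 1)
  # all mass in one off-diagonal cell: observed equals chance disagreement
  expect_equal(weighted_kappa(matrix(c(0, 0, 10, 0), 2, 2)), 0)
})

test_that("agreement labels follow the published bands", {
  expect_equal(kappa_label(c(0.21, 0.62, 1.0, 0.20, 0.45, -0.3)),
               c("fair", "substantial", "almost perfect", "slight",
                 "moderate", "slight"))
  expect_error(kappa_label(1.2), "-1, 1")
  expect_equal(icc_label(c(0.56, 0.81, 0.39, 0.60, 0.75)),
               c("fair", "excellent", "poor", "good", "excellent"))
})

test_that("ICC(3,1) is exact on identity and shift, with a sane CI", {
  x <- c(1.5, 2.2, 3.9, 4.1, 5.8, 7.2)
  same <- icc_consistency(make_pairs(x, x))
  expect_equal(same$icc, 1)
  shifted <- icc_consistency(make_pairs(x, x + 2.5))
  expect_equal(shifted$icc, 1)  # consistency ignores additive shifts

  withr::local_seed(5)
  y <- x + rnorm(6, sd = 0.5)
  res <- icc_consistency(make_pairs(x, y))
  expect_lte(res$ci_low, res$icc)
  expect_gte(res$ci_high, res$icc)
  expect_lte(res$icc, 1)

  expect_error(icc_consistency(make_pairs(rep(2, 5), rep(2, 5))),
               "between-subject")
})

test_that("Spearman handles monotone transforms and rejects constants", {
  x <- c(0.3, 1.2, 2.4, 3.3, 4.8, 6.1)
  expect_equal(spearman_r(make_pairs(x, x))$r, 1)
  expect_equal(spearman_r(make_pairs(x, exp(-x)))$r, -1)
  expect_error(spearman_r(make_pairs(x, rep(1, 6))), "constant")
})

test_that("Mann-Whitney separates and equates as expected", {
  same <- mann_whitney(1:10, 1:10)
  expect_gt(same$p, 0.9)
  sep <- mann_whitney(1:8, 101:108)
  expect_equal(sep$u, 0)  # all x below all y
  expect_lt(sep$p, 0.01)
})

test_that("Shapiro-Wilk screen flags lognormal but not normal samples", {
  withr::local_seed(21)
  norm <- shapiro_normality(rnorm(500))
  expect_true(norm$normal)
  lnorm <- shapiro_normality(rlnorm(500, sdlog = 1))
  expect_false(lnorm$normal)
  expect_error(shapiro_normality(c(1, 2)), "3 <= n")
})

test_that("adequacy cross-classification counts agreements", {
  a <- rep("INADEQUATE", 10)
  res <- adequacy_crossclass(a, a)
  expect_equal(res$correct_pct, 100)
  b <- rep(c("ADEQUATE", "INADEQUATE"), 5)
  flipped <- ifelse(b == "ADEQUATE", "INADEQUATE", "ADEQUATE")
  expect_equal(adequacy_crossclass(b, flipped)$correct_pct, 0)
  expect_error(adequacy_crossclass(a, a[-1]), "equal length")
  expect_error(adequacy_crossclass(a, rep("LOW", 10)), "ADEQUATE")
})

test_that("pair_intakes aligns respondents across sources", {
  spec <- cro_video_ffq()
  s1 <- dplyr::bind_rows(
    score_ffq(responses_with(spec, list(egg = 7), "a"), spec),
    score_ffq(responses_with(spec, list(egg = 14), "b"), spec),
    score_ffq(responses_with(spec, list(egg = 21), "c"), spec))
  s2 <- dplyr::bind_rows(
    score_ffq(responses_with(spec, list(egg = 7), "c", "FFQ2"), spec),
    score_ffq(responses_with(spec, list(egg = 14), "b", "FFQ2"), spec))
  p <- pair_intakes(s1, s2)
  expect_equal(p$respondent_id, c("b", "c"))
  expect_equal(p$x, c(2, 3) * 0.85)
  expect_equal(p$y, c(2, 1) * 0.85)
})

test_that("tidiers expose the result fields as tibbles", {
  withr::local_seed(9)
  x <- rlnorm(30)
  pairs <- make_pairs(x, x * exp(rnorm(30, sd = 0.3)))
  ba <- bland_altman(pairs)
  expect_equal(nrow(tidy(ba)), 30)
  expect_equal(glance(ba)$ba_index_pct, ba$ba_index_pct)
  q <- quartile_crossclass(pairs)
  expect_equal(sum(tidy(q)$n), 30)
  expect_equal(glance(q)$weighted_kappa, q$weighted_kappa)
  expect_s3_class(autoplot(ba), "ggplot")
})
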