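spec <- cro_video_ffq()

test_that("same parameters and seed reproduce the cohort exactly", {
  p <- cohort_params(n = 12, seed = 99)
  a <- generate_cohort(p, spec)
  b <- generate_cohort(p, spec)
  expect_equal(a$responses, b$responses)
  expect_equal(a$records, b$records)
  expect_equal(a$truth, b$truth)
  expect_equal(a$completers, b$completers)
  c2 <- generate_cohort(cohort_params(n = 12, seed = 100), spec)
  expect_false(isTRUE(all.equal(a$responses$servings_per_period,
                                c2$responses$servings_per_period)))
})

test_that("noise-free generation back-solves to the exact truth", {
  p <- cohort_params(n = 15, seed = 4, method_noise_sd = 0,
                     record_noise_sd = 0, record_bias = 1, dropout_rate = 0)
  cohort <- generate_cohort(p, spec)
  ffq1 <- score_ffq(
    cohort$responses[cohort$responses$administration == "FFQ1", ], spec)
  ffq2 <- score_ffq(
    cohort$responses[cohort$responses$administration == "FFQ2", ], spec)
  rec <- score_record(cohort$records, cohort$composition)

  # per-group recovery of the latent truth
  joined <- dplyr::inner_join(ffq1, cohort$truth,
                              by = c("respondent_id", "group_id"))
  expect_equal(joined$group_ug, joined$true_ug, tolerance = 1e-9)

  # the three methods agree with each other and with the latent totals
  t1 <- intake_totals(ffq1)$total_ug
  expect_equal(t1, intake_totals(ffq2)$total_ug, tolerance = 1e-9)
  expect_equal(t1, intake_totals(rec)$total_ug, tolerance = 1e-9)
  expect_equal(t1, cohort$truth_totals$true_total_ug, tolerance = 1e-9)
})

test_that("fish preferences stay within 1-2 products and drive the key", {
  cohort <- generate_cohort(cohort_params(n = 25, seed = 6), spec)
  per <- dplyr::count(cohort$preferences, respondent_id, item_id)
  expect_true(all(per$n %in% 1:2))
  # the same preference is used for both administrations
  resp <- cohort$responses
  sel1 <- resp[resp$administration == "FFQ1", c("respondent_id", "item_id",
                                                "selected_products")]
  sel2 <- resp[resp$administration == "FFQ2", c("respondent_id", "item_id",
                                                "selected_products")]
  joined <- dplyr::inner_join(sel1, sel2, by = c("respondent_id", "item_id"))
  expect_equal(joined$selected_products.x, joined$selected_products.y)
})

test_that("dropout thins completers binomially and deterministically", {
  p <- cohort_params(n = 200, seed = 17, dropout_rate = 0.4)
  cohort <- generate_cohort(p, spec)
  n_done <- length(cohort$completers)
  # fixed-seed value is exact; and it sits inside the Binomial(200, 0.6)
  # central 99.99% region [96, 144]
  expect_equal(n_done, length(generate_cohort(p, spec)$completers))
  expect_gte(n_done, qbinom(5e-5, 200, 0.6))
  expect_lte(n_done, qbinom(1 - 5e-5, 200, 0.6))
  # non-completers keep FFQ1 but lack FFQ2 and records
  resp <- cohort$responses
  expect_setequal(unique(resp$respondent_id[resp$administration == "FFQ1"]),
                  sprintf("r%04d", 1:200))
  expect_setequal(unique(resp$respondent_id[resp$administration == "FFQ2"]),
                  cohort$completers)
  expect_setequal(unique(cohort$records$respondent_id), cohort$completers)
})

test_that("generated FFQ medians recover the parameterized intake level", {
  p <- cohort_params(n = 2000, seed = 31, dropout_rate = 0)
  cohort <- generate_cohort(p, spec)
  ffq1 <- score_ffq(
    cohort$responses[cohort$responses$administration == "FFQ1", ], spec)
  sample_median <- median(intake_totals(ffq1)$total_ug)
  # independent oracle: direct Monte-Carlo draws of the sum of group-level
  # lognormals under the same parameters
  withr::local_seed(1234)
  draws <- matrix(0, 50000, length(p$group_mu))
  for (j in seq_along(p$group_mu)) {
    draws[, j] <- rlnorm(50000, p$group_mu[j], p$group_sigma[j])
  }
  oracle_median <- median(rowSums(draws))
  expect_lt(abs(sample_median - oracle_median) / oracle_median, 0.05)
})

test_that("retest correlation propagates to the scored Spearman r", {
  p <- cohort_params(n = 2000, seed = 8, retest_correlation = 0.8,
                     method_noise_sd = 0.3, dropout_rate = 0)
  cohort <- generate_cohort(p, spec)
  scores <- score_ffq(cohort$responses, spec)
  pairs <- pair_intakes(scores[scores$source == "FFQ1", ],
                        scores[scores$source == "FFQ2", ])
  observed <- spearman_r(pairs)$r

  # prediction from the generator's own error model: group-level lognormal
  # truth distributed over items by content weight, per-item correlated
  # multiplicative errors, Spearman of the resulting totals
  item_weight <- vapply(seq_len(nrow(spec$items)), function(j) {
    row <- spec$items[j, ]
    switch(row$selection_mode,
           FIXED = row$content_per_serving_ug,
           CHOOSE_FROM_LIST = mean(row$candidates[[1]]$content_per_serving_ug),
           FREE_TEXT = 0)
  }, numeric(1))
  item_group <- spec$items$group_id
  withr::local_seed(5678)
  nmc <- 20000
  totals <- function() {
    t1 <- t2 <- numeric(nmc)
    for (g in unique(item_group)) {
      gg <- rlnorm(nmc, p$group_mu[[g]], p$group_sigma[[g]])
      w <- item_weight[item_group == g]
      w <- w / sum(w)
      for (wi in w) {
        zs <- rnorm(nmc); za <- rnorm(nmc); zb <- rnorm(nmc)
        e1 <- p$method_noise_sd * (sqrt(0.8) * zs + sqrt(0.2) * za)
        e2 <- p$method_noise_sd * (sqrt(0.8) * zs + sqrt(0.2) * zb)
        t1 <- t1 + gg * wi * exp(e1)
        t2 <- t2 + gg * wi * exp(e2)
      }
    }
    list(t1, t2)
  }
  tt <- totals()
  predicted <- cor(rank(tt[[1]]), rank(tt[[2]]))
  expect_lt(abs(observed - predicted), 0.05)
})

test_that("the emulated study cohort matches its stated conditions", {
  cohort <- emulate_study_cohort(seed = 1)
  expect_equal(length(cohort$completers), 63)
  expect_equal(cohort$params$n, 106L)
  ffq1 <- score_ffq(
    cohort$responses[cohort$responses$administration == "FFQ1", ], spec)
  expect_true(all(intake_totals(ffq1)$total_ug > 0))
})

test_that("emulated medians sit in the calibration bands with the record lower", {
  n_seeds <- 12
  ffq_med <- rec_med <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    cohort <- emulate_study_cohort(seed = s)
    keep <- cohort$completers
    resp <- cohort$responses[cohort$responses$administration == "FFQ1" &
                               cohort$responses$respondent_id %in% keep, ]
    ffq_med[s] <- median(intake_totals(score_ffq(resp, spec))$total_ug)
    rec_med[s] <- median(intake_totals(
      score_record(cohort$records, cohort$composition))$total_ug)
  }
  expect_gte(mean(ffq_med >= 2.5 & ffq_med <= 4.5), 0.9)
  expect_gte(mean(rec_med >= 1.2 & rec_med <= 2.8), 0.9)
  # the record sits systematically below the questionnaire
  expect_gte(mean(rec_med < ffq_med), 0.95)
})

test_that("parameter validation rejects impossible settings", {
  expect_error(cohort_params(n = 0))
  expect_error(cohort_params(dropout_rate = 1))
  expect_error(cohort_params(retest_correlation = 1.2))
  expect_error(cohort_params(method_noise_sd = -0.1))
  p <- cohort_params(group_mu = c(only_group = 0))
  expect_error(generate_cohort(p, spec), "lack group")
})
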