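test_that("unbiased SD and CV_RF reproduce hand values and scale laws", {
  expect_equal(unbiased_sd(c(5, 5, 5)), 0)
  expect_equal(unbiased_sd(c(1, 2, 3)), 1)
  expect_equal(cv_rf(c(10, 10)), 0)
  expect_equal(cv_rf(c(1, 2, 3)), 50)
  set.seed(2)
  for (rep in 1:20) {
    x <- rnorm(sample(3:30, 1), 10, 3)
    expect_equal(unbiased_sd(x), oracle_sd(x), tolerance = 1e-12)
    expect_equal(cv_rf(3.7 * x), cv_rf(x), tolerance = 1e-10)
  }
  expect_error(unbiased_sd(5), class = "ivgpr_validation_error")
  expect_error(cv_rf(c(-1, 1)), class = "ivgpr_validation_error")
})

test_that("the Welch test matches the textbook formula and its conventions", {
  same <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  far <- welch_test(c(1, 2, 3), c(101, 102, 103) + rnorm(3, 0, 1e-3))
  expect_lt(far$p, 1e-6)

  a <- c(4.1, 5.0, 6.2); b <- c(7.3, 8.1, 9.9)
  got <- welch_test(a, b)
  want <- oracle_welch(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$df, want$df, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)

  const <- welch_test(c(2, 2), c(2, 2))
  expect_equal(const$p, 1)
  apart <- welch_test(c(2, 2), c(3, 3))
  expect_equal(apart$p, 0)
  expect_error(welch_test(1, c(1, 2)), class = "ivgpr_validation_error")
})

test_that("an all-identical response reduces the model to the intercept", {
  d <- tibble::tibble(trial_id = rep(sprintf("t%d", 1:6), each = 2),
                      donor_type = rep(c("RF_T", "RF_A"), each = 6),
                      value = 5)
  fit <- fit_trial_donor_model(d)
  expect_equal(fit$final_terms, "(intercept)")
})

test_that("nested designs drop the interaction and keep estimable terms", {
  set.seed(19)
  d <- tibble::tibble(
    trial_id = rep(sprintf("t%d", 1:8), each = 3),
    donor_type = rep(c("RF_T", "RF_A"), each = 12),
    value = rep(c(0, 4), each = 12) + rep(rnorm(8, 0, 0.3), each = 3) +
      rnorm(24, 0, 0.1))
  fit <- fit_trial_donor_model(d)
  expect_true(is.na(fit$p_interaction))
  expect_true(fit$nested)
  expect_true("donor_type" %in% fit$final_terms)
  expect_lt(fit$p_donor, 0.05)
  expect_false(is.na(fit$p_trial)) # trial effect estimable with replicates
  expect_lt(fit$welch$p, 0.05)
})

test_that("one value per trial reduces to the donor comparison", {
  set.seed(29)
  d <- tibble::tibble(trial_id = sprintf("t%d", 1:17),
                      donor_type = rep(c("RF_T", "RF_A"), c(5, 12)),
                      value = c(rnorm(5, 10, 0.5), rnorm(12, 10.2, 0.5)))
  fit <- fit_trial_donor_model(d)
  expect_true(is.na(fit$p_trial))
  expect_true(any(grepl("saturated", fit$notes)))
  expect_true(is.numeric(fit$p_donor))
  expect_error(fit_trial_donor_model(d[d$donor_type == "RF_T", ]),
               class = "ivgpr_validation_error")
})

test_that("a crossed design with a real interaction triggers the split", {
  set.seed(37)
  d <- tidyr::expand_grid(trial_id = sprintf("t%d", 1:4),
                          donor_type = c("RF_T", "RF_A"),
                          rep = 1:3)
  d$value <- 2 * (d$trial_id == "t1" & d$donor_type == "RF_T") +
    rnorm(nrow(d), 0, 0.1)
  fit <- fit_trial_donor_model(d)
  expect_false(fit$nested)
  expect_lt(fit$p_interaction, 0.05)
  expect_s3_class(fit$split, "tbl_df")
  expect_equal(nrow(fit$split), 2)
})

test_that("the repeatability report computes per-type and overall estimators", {
  per_trial <- tibble::tibble(
    trial_id = sprintf("t%d", 1:5),
    donor_type = c("RF_T", "RF_T", "RF_T", "RF_A", "RF_A"),
    tgp = c(10, 12, 14, 20, 22))
  rep_tbl <- repeatability_report(per_trial, "tgp")
  rft <- rep_tbl[rep_tbl$donor_type == "RF_T", ]
  expect_equal(rft$n, 3)
  expect_equal(rft$mean, 12)
  expect_equal(rft$sd, 2)
  expect_equal(rft$cv_rf, 100 * 2 / 12)
  expect_equal(rft$sem, 2 / sqrt(3))
  all_vals <- per_trial$tgp
  expect_equal(unique(rep_tbl$cv_all_trial_means),
               100 * oracle_sd(all_vals) / mean(all_vals))
  pooled_sd <- sqrt((2 * 2^2 + 1 * sqrt(2)^2) / 3)
  expect_equal(unique(rep_tbl$cv_all_within_type),
               100 * pooled_sd / mean(all_vals))
})
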