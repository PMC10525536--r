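grid5 <- seq(0, 40, by = 10)
series5 <- function(cum) tibble::tibble(time_min = grid5, cum_pressure_psi = cum)

test_that("profile is the pointwise mean with the earliest-maximum peak", {
  prof <- build_blank_profile(list(series5(c(0, 2, 4, 3, 3)),
                                   series5(c(0, 0, 2, 1, 1))))
  expect_equal(prof$mean_cum_psi, c(0, 1, 3, 2, 2))
  expect_equal(prof$peak_psi, 3)
  expect_equal(prof$peak_time_min, 20)
  expect_equal(prof$n_blanks, 2)
})

test_that("degenerate and idempotent profiles behave", {
  flat <- build_blank_profile(list(series5(rep(0, 5))))
  expect_equal(flat$mean_cum_psi, rep(0, 5))
  expect_equal(flat$peak_time_min, 0) # earliest tie at the first grid point
  expect_equal(flat$peak_psi, 0)

  b <- c(0, 1.5, 2.5, 2.0, 1.8)
  same <- build_blank_profile(list(series5(b), series5(b)))
  expect_equal(same$mean_cum_psi, b)

  expect_error(build_blank_profile(list()), class = "ivgpr_config_error")
})

test_that("a single blank can be selected by id", {
  blanks <- list(B1 = series5(c(0, 2, 4, 3, 3)), B2 = series5(c(0, 0, 2, 1, 1)))
  prof <- build_blank_profile(blanks, use_blank = "B2")
  expect_equal(prof$mean_cum_psi, c(0, 0, 2, 1, 1))
  expect_error(build_blank_profile(blanks, use_blank = "nope"),
               class = "ivgpr_config_error")
})

test_that("smoothing suppresses a spurious single-point early maximum", {
  noisy <- c(0, 5, 0.5, 1, 4, 4.2, 4.1, 3, 3)
  s <- tibble::tibble(time_min = seq(0, 80, by = 10), cum_pressure_psi = noisy)
  raw <- build_blank_profile(list(s))
  expect_equal(raw$peak_time_min, 10) # the spike wins without smoothing
  smoothed <- build_blank_profile(list(s), smooth_window = 3)
  expect_gt(smoothed$peak_time_min, 10)
})

test_that("the two-phase correction applies time-matched then peak subtraction", {
  prof <- build_blank_profile(list(series5(c(0, 2, 4, 3, 3))))
  expect_equal(prof$peak_psi, 4)
  out <- correct_sample(series5(c(0, 5, 10, 15, 20)), prof)
  # after the peak the blank MAXIMUM (4) is subtracted, not the declining values
  expect_equal(out$corrected_psi, c(0, 3, 6, 11, 16))
})

test_that("self-subtraction and zero-profile identities hold", {
  b <- c(0, 2, 4, 3, 3)
  prof <- build_blank_profile(list(series5(b)))
  self <- correct_sample(series5(b), prof)
  expect_equal(self$corrected_psi[1:3], c(0, 0, 0)) # up to the peak
  expect_true(all(self$corrected_psi[4:5] <= 0))
  expect_equal(attr(self, "n_negative"), 2)

  zero <- build_blank_profile(list(series5(rep(0, 5))))
  s <- c(0, 1, 4, 9, 16)
  expect_equal(correct_sample(series5(s), zero)$corrected_psi, s)
})

test_that("both phase formulas agree at the peak time itself", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:30, 1)
    grid <- seq(0, by = 10, length.out = n)
    blank <- cumsum(runif(n, 0, 1)) - cumsum(c(rep(0, floor(n / 2)), runif(ceiling(n / 2), 0, 0.8)))
    prof <- build_blank_profile(list(tibble::tibble(time_min = grid,
                                                    cum_pressure_psi = blank)))
    at_peak <- which(grid == prof$peak_time_min)
    expect_equal(prof$mean_cum_psi[at_peak], prof$peak_psi)
  }
})

test_that("monotone samples stay non-decreasing after the blank peak", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(6:40, 1)
    grid <- seq(0, by = 10, length.out = n)
    blank <- c(0, cumsum(rnorm(n - 1, 0.2, 0.5)))
    sample_cum <- cumsum(runif(n, 0, 2))
    prof <- build_blank_profile(list(tibble::tibble(time_min = grid,
                                                    cum_pressure_psi = blank)))
    out <- correct_sample(tibble::tibble(time_min = grid,
                                         cum_pressure_psi = sample_cum), prof)
    after <- grid > prof$peak_time_min
    if (sum(after) > 1) {
      expect_true(all(diff(out$corrected_psi[after]) >= -1e-12))
    }
  }
})

test_that("vectorized correction matches the per-point oracle on random series", {
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(4:25, 1)
    grid <- seq(0, by = 10, length.out = n)
    blank <- abs(cumsum(rnorm(n))) * sample(c(1, -1), 1, prob = c(0.8, 0.2))
    s <- cumsum(runif(n, 0, 3))
    prof <- build_blank_profile(list(tibble::tibble(time_min = grid,
                                                    cum_pressure_psi = blank)))
    out <- correct_sample(tibble::tibble(time_min = grid, cum_pressure_psi = s),
                          prof)
    expect_identical(out$corrected_psi, oracle_correct(s, prof$mean_cum_psi))
  }
})

test_that("a sample not covering the profile grid is rejected", {
  prof <- build_blank_profile(list(series5(c(0, 2, 4, 3, 3))))
  short <- tibble::tibble(time_min = c(0, 10, 20), cum_pressure_psi = c(0, 1, 2))
  expect_error(correct_sample(short, prof), class = "ivgpr_validation_error")
})
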