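test_that("tgp_at interpolates linearly and honours exact grid hits", {
  curve <- make_curve(c(0, 1, 2)) # grid 0, 10, 20 min
  expect_equal(tgp_at(curve, 0), 0)
  expect_equal(tgp_at(curve, 15 / 60), 1.5)
  expect_equal(tgp_at(curve, 10 / 60), 1)
  expect_error(tgp_at(curve, 0.5), class = "ivgpr_validation_error")
  expect_error(tgp_at(curve, -0.1), class = "ivgpr_validation_error")
})

test_that("interpolation error on a smooth curve stays below the curvature bound", {
  A <- 170; k <- 0.25
  grid_h <- seq(0, 24, by = 1 / 6)
  curve <- gas_curve(grid_h * 60, A * (1 - exp(-k * grid_h)))
  # linear interpolation error bound: max|f''| * h^2 / 8
  bound <- A * k^2 * (1 / 6)^2 / 8
  set.seed(3)
  for (hour in runif(50, 0, 24)) {
    expect_lt(abs(tgp_at(curve, hour) - A * (1 - exp(-k * hour))), bound + 1e-12)
  }
})

test_that("half-maximum is exactly half the end value by definition", {
  set.seed(5)
  for (rep in 1:20) {
    v <- cumsum(runif(145, 0, 2))
    p <- curve_parameters(make_curve(v))
    expect_identical(p$half_max, p$tgp_end / 2)
  }
  # printed per-type end values imply the printed half-maxima at one decimal
  p_t <- curve_parameters(make_curve(seq(0, 169.58, length.out = 145)))
  expect_equal(round(p_t$half_max, 1), 84.8)
})

test_that("a linear curve has constant rate, earliest-tie Tmax, interpolated half-time", {
  v <- 1.2 * seq(0, 24, by = 1 / 6) # 1.2 mL/g/h
  p <- curve_parameters(make_curve(v))
  expect_equal(p$vmax, 1.2)
  expect_equal(p$tmax_h, 0) # ties resolve to the earliest interval
  expect_equal(p$half_time_h, 12) # crossing found by interpolation
  expect_equal(p$tgp_end, 1.2 * 24)
})

test_that("degenerate curves follow the earliest-time conventions", {
  p <- curve_parameters(make_curve(rep(0, 145)))
  expect_equal(p$half_max, 0)
  expect_equal(p$half_time_h, 0)
  expect_equal(p$vmax, 0)
  expect_equal(p$tmax_h, 0)
  expect_error(curve_parameters(gas_curve(0, 0)), class = "ivgpr_validation_error")
  expect_error(curve_parameters(make_curve(c(0, 1, 2))), # spans only 20 min
               class = "ivgpr_validation_error")
})

test_that("sigmoid Tmax and Vmax agree with the analytic shape", {
  model <- curve_model("sigmoid", A = 200, C = 10, B = 3)
  grid_h <- seq(0, 24, by = 1 / 6)
  p <- curve_parameters(gas_curve(grid_h * 60, curve_value(model, grid_h)))
  # independent oracle: numerically differentiate the closed form finely
  fine <- seq(1e-3, 24, by = 1e-3)
  slope <- diff(curve_value(model, fine)) / 1e-3
  t_inflect <- fine[which.max(slope)]
  expect_lt(abs(p$tmax_h - t_inflect), 1 / 6 + 1e-9) # within one grid step
  expect_equal(p$vmax, max(slope), tolerance = 0.02)
})

test_that("strictly increasing curves cross the half-maximum once", {
  set.seed(9)
  for (rep in 1:10) {
    v <- cumsum(runif(145, 0.01, 1))
    p <- curve_parameters(make_curve(v))
    crossings <- sum(diff(v >= p$half_max) != 0)
    expect_equal(crossings, 1)
    expect_gte(p$half_time_h, 0)
    expect_lte(p$half_time_h, 24)
  }
})

test_that("vectorized Vmax/Tmax match a brute-force loop on random curves", {
  set.seed(13)
  for (rep in 1:50) {
    n <- sample(10:145, 1)
    v <- cumsum(runif(n, 0, 2))
    t_min <- seq(0, by = 10, length.out = n)
    p <- curve_parameters(gas_curve(t_min, v), end_hour = max(t_min) / 60,
                          hours = numeric(0))
    o <- oracle_vmax_tmax(t_min / 60, v)
    expect_identical(p$vmax, o$vmax)
    expect_identical(p$tmax_h, o$tmax_h)
  }
})

test_that("curve averaging is the pointwise mean with a shrinking SEM", {
  c1 <- make_curve(c(0, 2))
  expect_equal(average_curves(list(c1))$ml_per_g, c1$ml_per_g)
  c2 <- make_curve(c(0, 4))
  avg <- average_curves(list(c1, c2))
  expect_equal(avg$ml_per_g, c(0, 3))
  expect_error(average_curves(list()), class = "ivgpr_validation_error")

  # mean of N replicate noisy curves converges to the base curve, SEM ~ 1/sqrt(N)
  set.seed(21)
  base <- 170 * (1 - exp(-0.25 * seq(0, 24, by = 2)))
  noisy <- function() make_curve(base + rnorm(length(base), 0, 3),
                                 interval_min = 120)
  big <- average_curves(replicate(200, noisy(), simplify = FALSE))
  small <- average_curves(replicate(20, noisy(), simplify = FALSE))
  expect_lt(max(abs(big$ml_per_g - base)), 3 * 4 / sqrt(200))
  expect_equal(mean(big$sem[-1]) / mean(small$sem[-1]), sqrt(20 / 200),
               tolerance = 0.25)
})
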