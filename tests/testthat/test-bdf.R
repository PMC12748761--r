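cassava_dev <- dev_rate_params(14.86, 27, 40)

test_that("developmental rate is zero outside thresholds and peaks at the optimum", {
  expect_equal(dev_rate(14.86, cassava_dev), 0)
  expect_equal(dev_rate(10, cassava_dev), 0)
  expect_equal(dev_rate(40, cassava_dev), 0)
  expect_equal(dev_rate(45, cassava_dev), 0)
  grid <- seq(14.87, 39.99, by = 0.01)
  r <- dev_rate(grid, cassava_dev)
  expect_true(all(r > 0))
  expect_equal(grid[which.max(r)], 27, tolerance = 0.01)
  expect_equal(max(r), cassava_dev$rmax, tolerance = 1e-6)
  expect_error(dev_rate_params(30, 20, 40), "T0 < Topt < Tmax")
})

test_that("degree-day accumulation matches constant-day and quadrature oracles", {
  # whole day at the threshold: nothing accrues
  expect_equal(daily_physio_time(14.86, 14.86, cassava_dev), 0)
  expect_equal(daily_physio_time(12, 8, cassava_dev), 0)
  # constant day: integrand is constant, midpoint rule is exact
  for (tt in c(20, 27, 33)) {
    expect_equal(daily_physio_time(tt, tt, cassava_dev),
                 dev_rate(tt, cassava_dev) *
                   (cassava_dev$Topt - cassava_dev$T0) / cassava_dev$rmax)
  }
  # sinusoidal day vs a fine-grid quadrature of the same rate curve
  oracle <- function(tmax, tmin, p, n = 20000) {
    h <- (seq_len(n) - 0.5) / n
    th <- (tmax + tmin) / 2 - (tmax - tmin) / 2 * cos(2 * pi * h)
    mean(dev_rate(th, p)) * (p$Topt - p$T0) / p$rmax
  }
  got <- daily_physio_time(30, 20, cassava_dev)
  expect_equal(got, oracle(30, 20, cassava_dev), tolerance = 1e-4)
  got2 <- daily_physio_time(38, 16, cassava_dev)
  expect_equal(got2, oracle(38, 16, cassava_dev), tolerance = 1e-3)
  expect_error(daily_physio_time(10, 20, cassava_dev), "tmin > tmax")
})

test_that("acquisition follows the closed form and respects both bounds", {
  expect_equal(acquisition(1, 0, 0.5), 0)
  expect_equal(acquisition(1, 2, 0.5), 1 - exp(-1))
  # saturation: S -> D as alpha R / D grows
  expect_lt(abs(acquisition(1, 100, 0.5) - 1), 1e-20)
  expect_error(acquisition(0, 1, 0.5), "demand")
  # property: S < D and S <= alpha R over random admissible inputs
  set.seed(11)
  for (i in 1:200) {
    D <- runif(1, 1e-6, 50)
    R <- runif(1, 0, 200)
    a <- runif(1, 1e-3, 1)
    S <- acquisition(D, R, a)
    expect_lte(S, D)
    if (a * R / D < 30) expect_lt(S, D)
    expect_lte(S, a * R + 1e-12)
    expect_gte(S, 0)
  }
  # small-resource linearity: S ~ alpha R within 1% when alpha R / D <= 0.01
  D <- 5; a <- 0.4; R <- 0.01 * D / a
  expect_equal(acquisition(D, R, a), a * R, tolerance = 0.01)
})

test_that("temperature scalar is 1 at optimum, 0 at bounds, unimodal", {
  p <- scalar_params(15, 28, 35)
  expect_equal(temp_scalar(28, p), 1)
  expect_equal(temp_scalar(15, p), 0)
  expect_equal(temp_scalar(35, p), 0)
  expect_equal(temp_scalar(40, p), 0)
  # midway between lower and optimum: direct evaluation of the parabola
  mid <- (15 + 28) / 2
  expect_equal(temp_scalar(mid, p), 1 - ((mid - 28) / (28 - 15))^2)
  grid <- seq(10, 40, by = 0.25)
  s <- temp_scalar(grid, p)
  expect_true(all(s >= 0 & s <= 1))
  expect_error(scalar_params(30, 20, 40), "lower < opt < upper")
})

test_that("mortality rate is minimal at the optimum with monotone limbs", {
  p <- mortality_params(0.02, 27, 0.001, 0.004)
  expect_equal(mortality_rate(27, p), 0.02)
  expect_gte(mortality_rate(37, p), mortality_rate(32, p))
  expect_gte(mortality_rate(17, p), mortality_rate(22, p))
  # quadratic-limb formula against brute-force evaluation on a grid
  grid <- seq(12, 42, by = 3)
  brute <- vapply(grid, function(tt)
    0.02 + if (tt < 27) 0.001 * (27 - tt)^2 else 0.004 * (tt - 27)^2,
    numeric(1))
  expect_equal(mortality_rate(grid, p), brute)
  expect_true(all(mortality_rate(grid, p) >= 0.02))
})

test_that("pathogen scalar gates on rain and humidity and half-saturates", {
  expect_equal(pathogen_scalar(0, 30), 0)
  expect_equal(pathogen_scalar(0, 95), 0)
  expect_equal(pathogen_scalar(500, 30, rh_lo = 40), 0)
  expect_gt(pathogen_scalar(1000, 95), 0.98)
  # rain at the half-saturation constant under saturating humidity
  expect_equal(pathogen_scalar(15, 95, half_rain = 15), 0.5)
  r <- seq(0, 100, by = 5)
  s <- pathogen_scalar(r, 80)
  expect_true(all(diff(s) >= 0))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("fecundity is the gated product of profile, scalar and supply", {
  pr <- reproduction_profile(20, 10, 80)
  ts <- scalar_params(15, 28, 35)
  expect_equal(fecundity(10, 28, 1, pr, ts), 0)    # before first reproduction
  expect_equal(fecundity(100, 28, 0, pr, ts), 0)   # starved
  expect_equal(fecundity(100, 28, 1, pr, ts), 10)  # peak age, all scalars 1
  expect_equal(reproduction_rate(100, pr), 10)
  expect_true(all(fecundity(seq(0, 600, 10), 25, 0.7, pr, ts) >= 0))
})
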