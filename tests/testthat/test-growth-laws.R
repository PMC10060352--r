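test_that("stress modifier is the piecewise-linear arrest function", {
  expect_equal(stress_modifier(0, -2), 1)
  expect_equal(stress_modifier(-2, -2), 0)
  expect_equal(stress_modifier(-1, -2), 0.5)       # midpoint of the ramp
  expect_equal(stress_modifier(5, -2), 1)
  expect_equal(stress_modifier(-10, -2), 0)
  # degenerate threshold: indicator of non-negative stress
  expect_equal(stress_modifier(c(-1, 0, 1), 0), c(0, 1, 1))
  expect_error(stress_modifier(0, 1), "non-positive")
})

test_that("stress modifier is weakly increasing and bounded in [0, 1]", {
  set.seed(23)
  for (i in 1:20) {
    sh <- -runif(1, 0.01, 200)
    s <- sort(rnorm(200, sd = 100))
    n <- stress_modifier(s, sh)
    expect_true(all(n >= 0 & n <= 1))
    expect_true(all(diff(n) >= 0))
  }
})

test_that("M1 rate is linear in the nutrient gap", {
  dp <- dimensionless_params(chat = 4 / 5)
  expect_equal(growth_rate_m1(4 / 5, dp), 0)
  expect_equal(growth_rate_m1(1, dp), 1 / 5)
  expect_equal(growth_rate_m1(0, dp), -0.8)
  # dimensional: k (c - c_hat)
  p <- spheroid_params(k = 3, c_inf = 2, c_hat = 1)
  expect_equal(growth_rate_m1(2, p), 3)
})

test_that("M2 modulates growth but not necrotic decay", {
  dp <- dimensionless_params(chat = 0.5, sigmahat_mu = -2)
  # too much compression: growth prohibited
  expect_equal(growth_rate_m2(0.8, -3, dp), 0)
  # necrotic decay unaltered by stress
  expect_equal(growth_rate_m2(0.2, -50, dp), -0.3)
  # tension-free: identical to M1
  expect_equal(growth_rate_m2(0.9, 0.5, dp), growth_rate_m1(0.9, dp))
  # half-arrest on the ramp
  expect_equal(growth_rate_m2(0.7, -1, dp), 0.5 * 0.2)
})

test_that("M3-M5 rates are non-negative and respect the necrotic front", {
  dp <- dimensionless_params(chat = 0.5, sigmahat_mu = -2, beta = 2)
  # inside the front: zero regardless of stress or nutrient
  expect_equal(growth_rate_m3(0.9, 1, R = 0.2, R_N = 0.5, dp), 0)
  expect_equal(growth_rate_m4(0.9, 1, R = 0.2, R_N = 0.5, dp), 0)
  expect_equal(growth_rate_m5(0.9, 1, 1, R = 0.2, R_N = 0.5, dp), 0)
  # outside, unstressed: reduces to M1
  expect_equal(growth_rate_m3(0.9, 0.1, R = 0.9, R_N = 0.5, dp), 0.4)
  expect_equal(growth_rate_m4(0.9, 0.1, R = 0.9, R_N = 0.5, dp), 0.4)
  # clamping: marginally sub-threshold nutrient cannot give decay
  expect_equal(growth_rate_m3(0.499, 0, R = 0.9, R_N = 0.5, dp), 0)
  # arrested everywhere when the measure passes the threshold
  expect_equal(growth_rate_m4(0.9, -2.5, R = 0.9, R_N = 0, dp), 0)
  # M5: local factor at sigma_hat / beta vanishes
  expect_equal(growth_rate_m5(0.9, 0, -1, R = 0.9, R_N = 0, dp), 0)
  # M5 reduces to M4 under local tension
  expect_equal(growth_rate_m5(0.9, -1, 0.3, R = 0.9, R_N = 0, dp),
               growth_rate_m4(0.9, -1, R = 0.9, R_N = 0, dp))
  # non-negativity over random inputs
  set.seed(31)
  for (i in 1:10) {
    args <- list(runif(1, 0, 1), runif(1, -5, 1), runif(1, -5, 1))
    expect_gte(growth_rate_m5(args[[1]], args[[2]], args[[3]],
                              R = runif(1), R_N = runif(1), dp), 0)
  }
})

test_that("global stress measure is the componentwise minimum", {
  expect_equal(global_stress_measure(rep(0, 5), rep(0, 5)), 0)
  expect_equal(global_stress_measure(rep(-1, 5), rep(-3, 5)), -3)
  set.seed(5)
  sr <- rnorm(50)
  sth <- rnorm(50)
  expect_equal(global_stress_measure(sr, sth), min(c(sr, sth)))
})

test_that("necrotic front is a non-decreasing running maximum", {
  dp <- dimensionless_params(chat = 4 / 5)
  grid <- spheroid_grid(1, n = 200)
  ones <- rep(1, length(grid$R))

  # fully perfused: unchanged
  st_small <- spheroid_state(grid, ones)
  expect_equal(update_necrotic_front(0.1, st_small, dp), 0.1)

  # growth past onset then shrink back: the maximum is retained
  st_big <- spheroid_state(grid, 1.4 * ones)     # b = 1.4 > sqrt(6/5)
  R_N1 <- update_necrotic_front(0, st_big, dp)
  expect_gt(R_N1, 0)
  expect_equal(update_necrotic_front(R_N1, st_small, dp), R_N1)

  # monotonicity under arbitrary growth/shrink sequences
  set.seed(17)
  R_N <- 0
  for (g in runif(20, 0.8, 1.6)) {
    st <- spheroid_state(grid, g * ones)
    R_new <- update_necrotic_front(R_N, st, dp)
    expect_gte(R_new, R_N)
    expect_lte(R_new, grid$B)
    R_N <- R_new
  }
})

test_that("front position is consistent with the closed-form radius", {
  # homogeneous stretch g: r = g R, so R* = r* / g
  dp <- dimensionless_params(chat = 4 / 5)
  grid <- spheroid_grid(1, n = 400)
  g <- 1.5
  st <- spheroid_state(grid, rep(g, length(grid$R)))
  r_star <- necrosis_boundary_radius(g, dp)
  expect_equal(update_necrotic_front(0, st, dp), r_star / g,
               tolerance = 1e-6)
})
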