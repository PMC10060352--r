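test_that("homogeneous growth is stress-free; boundary condition is exact", {
  grid <- spheroid_grid(1, n = 100)
  st <- spheroid_state(grid, gamma = rep(2, length(grid$R)))
  dp0 <- dimensionless_params(chat = 0.5, kappa_mu = 0)
  prof <- radial_stress(st, dp0)
  expect_equal(prof$sigma_r, rep(0, length(grid$R)))
  expect_equal(prof$sigma_theta, prof$sigma_r)

  # gamma = g, kappa = mu, b = 2B: zero integrand, sigma_r = -mu everywhere
  dp1 <- dimensionless_params(chat = 0.5, kappa_mu = 1)
  prof1 <- radial_stress(st, dp1)
  expect_equal(prof1$boundary_value, -1)
  expect_equal(prof1$sigma_r, rep(-1, length(grid$R)))
})

test_that("radial stress agrees with a 10x-resolution independent run", {
  dp <- dimensionless_params(chat = 0.5, kappa_mu = 0)
  s_coarse <- radial_stress(quadratic_gamma_state(400), dp)
  s_fine <- radial_stress(quadratic_gamma_state(4000), dp)
  expect_equal(s_coarse$sigma_r[1], s_fine$sigma_r[1], tolerance = 1e-4)
})

test_that("hoop stress follows the algebraic neo-Hookean identity", {
  # alpha = 2, mu = 1, sigma_r = 0: sigma_theta = 4 - 1/16 = 3.9375
  expect_equal(0 + (2^2 - 2^-4), 3.9375)
  st <- quadratic_gamma_state(400)
  dp <- dimensionless_params(chat = 0.5)
  prof <- radial_stress(st, dp)
  alpha <- elastic_stretch(st)
  expect_equal(prof$sigma_theta - prof$sigma_r, alpha^2 - alpha^(-4))
  # sign rule: sigma_theta - sigma_r has the sign of alpha - 1
  expect_true(all(sign(prof$sigma_theta - prof$sigma_r)[-1] ==
                    sign(alpha - 1)[-1]))
})

test_that("derivative form of the hoop stress holds to discretisation order", {
  st <- quadratic_gamma_state(800)
  dp <- dimensionless_params(chat = 0.5)
  prof <- radial_stress(st, dp)
  i <- seq(5, length(st$r) - 4)
  dsr_dr <- (prof$sigma_r[i + 1] - prof$sigma_r[i - 1]) /
    (st$r[i + 1] - st$r[i - 1])
  lhs <- prof$sigma_r[i] + st$r[i] / 2 * dsr_dr
  expect_equal(lhs, prof$sigma_theta[i], tolerance = 1e-3)
})

test_that("residual profiles obey the traction-free and mean-stress identities", {
  dp <- dimensionless_params(chat = 0.5, kappa_mu = 2, sigmahat_mu = -1)
  st <- quadratic_gamma_state(800)
  res <- residual_profiles(st, dp)
  n <- length(st$r)
  expect_identical(res$boundary_value, 0)
  expect_equal(res$sigma_r[n], 0)

  # homogeneous growth: residual fields vanish
  grid <- spheroid_grid(1, n = 50)
  res0 <- residual_profiles(spheroid_state(grid, rep(3, length(grid$R))), dp)
  expect_equal(res0$sigma_r, rep(0, length(grid$R)))

  # monotone gamma: radial residual decreasing in R, boundary hoop <= 0
  expect_true(all(diff(res$sigma_r) <= 1e-10))
  expect_lte(res$boundary_hoop, 0)
  expect_false(res$tensile_boundary)

  # mean-stress identity: volume integral of the trace vanishes
  tr <- (res$sigma_r + 2 * res$sigma_theta) * st$r^2
  I <- sum(diff(st$r) * (tr[-1] + tr[-n]) / 2)
  I_abs <- sum(diff(st$r) * (abs(tr)[-1] + abs(tr)[-n]) / 2)
  expect_lt(abs(I) / I_abs, 1e-3)
})

test_that("stress profiles export to CSV in units of mu", {
  st <- quadratic_gamma_state(30)
  dp <- dimensionless_params(chat = 0.5)
  prof <- radial_stress(st, dp)
  path <- withr::local_tempfile(fileext = ".csv")
  write_stress_csv(prof, st, path)
  df <- read.csv(path)
  expect_named(df, c("R", "r", "sigma_r", "sigma_theta"))
  expect_equal(df$sigma_r, prof$sigma_r)
})
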