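test_that("one M1 step is forward-consistent with the growth law", {
  dp <- dimensionless_params(chat = 0.8)
  grid <- spheroid_grid(1, n = 100)
  st <- spheroid_state(grid)
  dt <- 1e-4
  st1 <- spheroid_step(st, "M1", dp, dt)
  c0 <- (grid$R^2 - 1) / 6 + 1
  expect_lt(max(abs(log(st1$gamma) - dt * (c0 - 0.8))), 100 * dt^2)
  expect_equal(st1$t, dt)
})

test_that("M4 under a super-threshold global measure is an exact fixed point", {
  # homogeneous stretch 2 with kappa/mu = 2 gives sigma_r = -2 <= sigma_hat
  dp <- dimensionless_params(chat = 0.5, kappa_mu = 2, sigmahat_mu = -1)
  grid <- spheroid_grid(1, n = 100)
  st <- spheroid_state(grid, rep(2, length(grid$R)))
  st1 <- spheroid_step(st, "M4", dp, 0.1)
  expect_identical(st1$gamma, st$gamma)
  expect_identical(st1$r, st$r)
})

test_that("time refinement converges on the nutrient-only problem", {
  dp <- figure_params("fig3")
  b_of <- function(dt) {
    tr <- simulate_spheroid(dp, "M1", t_end = 2, dt = dt, n = 300,
                            resolution_warn = 0)
    tail(tr$series$b, 1)
  }
  # reference at dt/16 isolates the temporal discretisation error
  b_ref <- b_of(0.0025)
  errs <- abs(vapply(c(0.04, 0.02, 0.01), b_of, 0) - b_ref)
  expect_true(all(diff(errs) < 0))
  expect_equal(b_ref, closed_form_radius(2, dp), tolerance = 1e-3)
})

test_that("M1 relaxes monotonically onto the steady state from above", {
  dp <- dimensionless_params(chat = 4 / 5, B_over_L = 2)  # B > b_N*
  traj <- simulate_spheroid(dp, "M1", t_end = 15, resolution_warn = 0)
  b <- traj$series$b
  expect_true(all(diff(b) <= 1e-12))
  expect_equal(tail(b, 1), sqrt(3), tolerance = 1e-3)
})

test_that("snapshots reproduce the recorded diagnostics exactly", {
  dp <- figure_params("fig9")
  traj <- simulate_spheroid(dp, "M5", t_end = 3, dt = 0.01, n = 150,
                            snapshot_stride = 50, resolution_warn = 0)
  for (i in seq_along(traj$snapshots)) {
    st <- state_at(traj, i)
    j <- which(abs(traj$series$t - st$t) < 1e-12)
    prof <- radial_stress(st, dp)
    expect_identical(tail(st$r, 1), traj$series$b[j])
    expect_identical(prof$sigma_r[1], traj$series$sigma_r_centre[j])
    expect_identical(global_stress_measure(prof$sigma_r, prof$sigma_theta),
                     traj$series$global_measure[j])
  }
})

test_that("trajectories are deterministic and scale-invariant", {
  dp <- figure_params("fig9")
  t1 <- simulate_spheroid(dp, "M5", t_end = 2, dt = 0.01, n = 100,
                          resolution_warn = 0)
  t2 <- simulate_spheroid(dp, "M5", t_end = 2, dt = 0.01, n = 100,
                          resolution_warn = 0)
  expect_identical(t1$series, t2$series)

  # consistent dimensional rescaling (lengths x2 via D x4) leaves the
  # dimensionless trajectory unchanged
  p1 <- spheroid_params(c_hat = 0.8, B = 1, D = 1, lam = 1)
  p2 <- spheroid_params(c_hat = 0.8, B = 2, D = 4, lam = 1)
  s1 <- simulate_spheroid(p1, "M1", t_end = 2, dt = 0.01, n = 100,
                          resolution_warn = 0)$series
  s2 <- simulate_spheroid(p2, "M1", t_end = 2, dt = 0.01, n = 100,
                          resolution_warn = 0)$series
  expect_equal(s1$b, s2$b, tolerance = 1e-12)
})

test_that("unbounded growth of the stretch halts cleanly with a flag", {
  dp <- figure_params("fig3")
  traj <- simulate_spheroid(dp, "M1", t_end = 500, dt = 0.05, n = 60,
                            gamma_max = 1e6, resolution_warn = 0)
  expect_identical(traj$status, "unbounded_growth_stretch")
  expect_lt(tail(traj$series$t, 1), 500)
})

test_that("material paths show interior drift toward the necrotic core", {
  dp <- figure_params("fig3")
  traj <- simulate_spheroid(dp, "M1", t_end = 20, dt = 0.01, n = 300,
                            snapshot_stride = 100, resolution_warn = 0)
  paths <- material_paths(traj, c(0, 0.5, 1))
  # centre fixed, boundary equals the growth curve
  expect_equal(paths$R_0, rep(0, nrow(paths)))
  j <- match(paths$t, traj$series$t)
  expect_equal(paths$R_1, traj$series$b[j], tolerance = 1e-12)
  # after reaching steady b, the interior material point moves inward
  late <- paths$t > 10
  expect_true(all(diff(paths$R_0.5[late]) < 0))
  expect_error(material_paths(traj, 2), "R_values")
})

test_that("boundary stress history starts at zero in free suspension", {
  dp <- figure_params("fig3")
  traj <- simulate_spheroid(dp, "M1", t_end = 1, dt = 0.01, n = 100,
                            snapshot_stride = 10, resolution_warn = 0)
  h <- boundary_stress_history(traj)
  expect_equal(h$sigma_theta_b[1], 0)
  expect_equal(h$sigma_r_b, rep(0, nrow(h)))  # kappa = 0
})

test_that("integration failures carry the last valid state", {
  dp <- dimensionless_params(chat = 0.5)
  grid <- spheroid_grid(1, n = 20)
  st <- spheroid_state(grid)
  st$gamma[5] <- 1e308  # engineered overflow in gamma^6
  err <- tryCatch(spheroid_step(st, "M1", dp, 1),
                  morphospheroid_integration_error = function(e) e)
  expect_s3_class(err, "morphospheroid_integration_error")
  expect_s3_class(err$last_state, "spheroid_state")
})
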