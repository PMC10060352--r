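test_that("growth CSVs are read, validated and unit-converted", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,radius", "0,100", "5,150"), path)
  ds <- read_growth_csv(path)
  expect_s3_class(ds, "growth_dataset")
  expect_equal(ds$radius, c(100, 150))

  ds2 <- read_growth_csv(path, measure = "diameter")
  expect_equal(ds2$radius, c(50, 75))

  ds3 <- read_growth_csv(path, time_scale = 1 / 24, radius_scale = 1e-3)
  expect_equal(ds3$time, c(0, 5 / 24))
  expect_equal(ds3$radius, c(0.1, 0.15))

  writeLines("time,radius", path)
  expect_error(read_growth_csv(path), "data row")
  writeLines(c("time,radius", "0,100", "0,150"), path)
  expect_error(read_growth_csv(path), "increasing")
  writeLines(c("time,radius", "0,100", "5,-1"), path)
  expect_error(read_growth_csv(path), "non-positive")
  writeLines(c("time,radius", "0,100", "oops,150"), path)
  expect_error(read_growth_csv(path), "line 3")
})

test_that("objective vanishes at the generating truth and rises away from it", {
  cond <- dimensionless_params(chat = 0.5, B_over_L = 0.6)
  ds <- synthesize_growth_data(list(d = cond), law = "M1",
                               times = seq(0, 8, by = 1), noise_sd = 0,
                               seed = 2)[[1]]
  fs <- fit_spec("M1", fixed = list(L = 1, T = 1, chat = 0.5),
                 free_shared = "B", bounds = list(B = c(0.1, 2)))
  at_truth <- growth_objective(c(B = 0.6), fs, list(ds))
  expect_lt(at_truth, 1e-16)
  expect_gt(growth_objective(c(B = 0.66), fs, list(ds)), at_truth)
  expect_gt(growth_objective(c(B = 0.54), fs, list(ds)), at_truth)

  # a single observation at t0 is matched exactly by B
  one <- growth_dataset("one", 0, 0.6)
  expect_equal(growth_objective(c(B = 0.6), fs, list(one)), 0)

  # invariant to dataset ordering
  ds2 <- synthesize_growth_data(
    list(d2 = dimensionless_params(chat = 0.5, B_over_L = 0.4)),
    law = "M1", times = seq(0, 8, by = 1), noise_sd = 0, seed = 2)[[1]]
  expect_identical(growth_objective(c(B = 0.6), fs, list(ds, ds2)),
                   growth_objective(c(B = 0.6), fs, list(ds2, ds)))
})

test_that("synthetic data are deterministic and ordered by stiffness", {
  a <- synthesize_growth_data(seed = 9, times = seq(0, 6, by = 2),
                              dt = 0.1, n = 40)
  b <- synthesize_growth_data(seed = 9, times = seq(0, 6, by = 2),
                              dt = 0.1, n = 40)
  expect_identical(lapply(a, `[[`, "radius"), lapply(b, `[[`, "radius"))
  expect_identical(a[[1]]$condition, "free")
  expect_identical(a[[2]]$condition, "embedded")

  # noiseless curves: stiffer conditions end smaller
  noiseless <- synthesize_growth_data(
    synthetic_conditions(kappa_mu = c(0.1, 0.3, 1)),
    times = seq(0, 12, by = 3), noise_sd = 0, seed = 1, dt = 0.1, n = 40)
  finals <- vapply(noiseless, function(d) tail(d$radius, 1), 0)
  expect_true(all(diff(finals) < 0))
  # noiseless samples are exact model curves (monotone growth under M5)
  for (d in noiseless) expect_true(all(diff(d$radius) > -1e-12))
})

test_that("fits with no free parameters evaluate without search", {
  cond <- dimensionless_params(chat = 0.5, B_over_L = 0.6)
  ds <- synthesize_growth_data(list(d = cond), law = "M1",
                               times = seq(0, 4, by = 1), noise_sd = 0,
                               seed = 3)[[1]]
  fs <- fit_spec("M1", fixed = list(L = 1, T = 1, chat = 0.5, B = 0.6))
  fit <- fit_growth(list(ds), fs)
  expect_length(fit$par, 0)
  expect_lt(fit$objective, 1e-16)
  expect_equal(fit$objective, sum(fit$per_dataset_rss))
})

test_that("single-dataset recovery is exact on noiseless data", {
  cond <- dimensionless_params(chat = 0.5, B_over_L = 0.6)
  ds <- synthesize_growth_data(list(d = cond), law = "M1",
                               times = seq(0, 10, by = 1), noise_sd = 0,
                               seed = 4, dt = 0.05, n = 80)[[1]]
  fs <- fit_spec("M1", fixed = list(L = 1, T = 1),
                 free_shared = c("chat", "B"),
                 bounds = list(chat = c(0.1, 0.9), B = c(0.1, 2)),
                 dt = 0.05, n = 80)
  fit <- fit_growth(list(ds), fs, n_starts = 3, seed = 5, maxit = 300)
  expect_lt(abs(fit$par[["chat"]] - 0.5) / 0.5, 0.01)
  expect_lt(abs(fit$par[["B"]] - 0.6) / 0.6, 0.01)
  expect_identical(fit$convergence, 0L)
  expect_equal(nrow(fit$starts), 3L)

  # determinism
  fit2 <- fit_growth(list(ds), fs, n_starts = 3, seed = 5, maxit = 300)
  expect_identical(fit$par, fit2$par)

  curves <- fitted_curves(fit, fs, list(ds))
  expect_equal(curves$d$radius_fit, curves$d$radius_obs, tolerance = 1e-4)
})
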