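# Growth-curve I/O and multi-condition least-squares fitting. The fitting
# convention mirrors the multi-condition experiment it emulates: all
# biological and mechanical parameters are shared across growth curves,
# with only the initial radius B and the external stiffness kappa allowed
# to vary between conditions; free-suspension curves force kappa = 0.

#' Read a growth curve from CSV
#'
#' Expects a header and at least two columns, read as (time, size). Sizes
#' may be declared as diameters, in which case they are halved. Unit
#' scaling factors convert the file's units into the working units (e.g.
#' hours to days, micrometres to units of `L`).
#'
#' @param path CSV file path.
#' @param measure `"radius"` (default) or `"diameter"`.
#' @param time_scale,radius_scale multiplicative conversion applied to the
#'   columns after reading (and after halving, for diameters).
#' @param label dataset label; defaults to the file name.
#' @param condition `"embedded"` (default) or `"free"` (free suspension,
#'   which pins `kappa = 0` during fitting).
#' @return Object of class `growth_dataset`: list with `label`, `time`,
#'   `radius`, `condition`.
#' @export
read_growth_csv <- function(path, measure = c("radius", "diameter"),
                            time_scale = 1, radius_scale = 1,
                            label = basename(path),
                            condition = c("embedded", "free")) {
  measure <- match.arg(measure)
  condition <- match.arg(condition)
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) stop("cannot parse '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0 || ncol(df) < 2) {
    stop("'", path, "': need at least two columns and one data row",
         call. = FALSE)
  }
  time <- suppressWarnings(as.numeric(df[[1]]))
  size <- suppressWarnings(as.numeric(df[[2]]))
  bad <- which(!is.finite(time) | !is.finite(size))
  if (length(bad)) {
    stop("'", path, "': malformed row at line ", bad[1] + 1L, call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("'", path, "': times not strictly increasing at line ",
         which(diff(time) <= 0)[1] + 2L, call. = FALSE)
  }
  if (any(size <= 0)) {
    stop("'", path, "': non-positive size at line ",
         which(size <= 0)[1] + 1L, call. = FALSE)
  }
  radius <- if (measure == "diameter") size / 2 else size
  growth_dataset(label, time * time_scale, radius * radius_scale, condition)
}

#' Construct a growth dataset in memory
#'
#' @param label dataset label.
#' @param time strictly increasing observation times.
#' @param radius positive observed radii.
#' @param condition `"embedded"` or `"free"`.
#' @return Object of class `growth_dataset`.
#' @export
growth_dataset <- function(label, time, radius,
                           condition = c("embedded", "free")) {
  condition <- match.arg(condition)
  stopifnot(length(time) == length(radius), length(time) >= 1,
            all(diff(time) > 0), all(radius > 0))
  structure(list(label = as.character(label), time = as.numeric(time),
                 radius = as.numeric(radius), condition = condition),
            class = "growth_dataset")
}

#' Fit specification
#'
#' Declares the growth law, the fixed (shared) parameter values, which
#' parameters are free, their bounds, the residual type and the simulator
#' controls used inside the objective. Shared parameter names are `"L"`,
#' `"T"`, `"chat"`, `"sigmahat_mu"`, `"beta"`, `"kappa_mu"`, `"B"`
#' (initial radius, in the data's length units). Per-dataset free
#' parameters are restricted to `"B"` and `"kappa_mu"` and are expanded to
#' one entry per dataset, named `<name>__<label>`.
#'
#' @param law law id (`"M1"`..`"M5"`).
#' @param fixed named list of fixed parameter values; must include any
#'   shared parameter that is not free. Defaults: `L = 1`, `T = 1`,
#'   `beta = 1`, `kappa_mu = 0`, `sigmahat_mu = 0`.
#' @param free_shared character vector of shared free parameter names.
#' @param free_per_dataset character vector among `c("B", "kappa_mu")`.
#' @param bounds named list of `c(lower, upper)` per free parameter name
#'   (base name for per-dataset parameters).
#' @param residual `"radius"` (default), `"volume"` or `"relative"`.
#' @param dt,n simulator controls used in the objective (coarser defaults
#'   than [simulate_spheroid()] to keep fitting affordable; the same
#'   controls must be used when generating synthetic truth so that
#'   discretisation bias cancels).
#' @return Object of class `fit_spec`.
#' @export
fit_spec <- function(law, fixed = list(), free_shared = character(),
                     free_per_dataset = character(), bounds = list(),
                     residual = c("radius", "volume", "relative"),
                     dt = 0.05, n = 80) {
  residual <- match.arg(residual)
  law <- growth_law(law)$id
  shared_names <- c("L", "T", "chat", "sigmahat_mu", "beta", "kappa_mu", "B")
  if (!all(free_shared %in% shared_names)) {
    stop("unknown shared parameter in free_shared", call. = FALSE)
  }
  if (!all(free_per_dataset %in% c("B", "kappa_mu"))) {
    stop("per-dataset free parameters are restricted to B and kappa_mu",
         call. = FALSE)
  }
  if (length(intersect(free_shared, free_per_dataset))) {
    stop("a parameter cannot be both shared-free and per-dataset-free",
         call. = FALSE)
  }
  defaults <- list(L = 1, T = 1, beta = 1, kappa_mu = 0, sigmahat_mu = 0)
  fixed <- utils::modifyList(defaults, fixed)
  need <- setdiff(c(free_shared, free_per_dataset), names(bounds))
  if (length(need)) {
    stop("missing bounds for: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  structure(list(law = law, fixed = fixed, free_shared = free_shared,
                 free_per_dataset = free_per_dataset, bounds = bounds,
                 residual = residual, dt = dt, n = n),
            class = "fit_spec")
}

free_param_names <- function(fitspec, datasets) {
  per <- unlist(lapply(fitspec$free_per_dataset, function(nm) {
    labs <- vapply(datasets, `[[`, "", "label")
    # kappa is pinned at 0 for free-suspension datasets, never fitted
    if (nm == "kappa_mu") {
      labs <- labs[vapply(datasets, `[[`, "", "condition") != "free"]
    }
    if (length(labs)) paste0(nm, "__", labs) else character()
  }))
  c(fitspec$free_shared, per)
}

bounds_for <- function(fitspec, par_names) {
  base <- sub("__.*$", "", par_names)
  lo <- vapply(base, function(b) fitspec$bounds[[b]][1], 0)
  hi <- vapply(base, function(b) fitspec$bounds[[b]][2], 0)
  list(lower = lo, upper = hi)
}

dataset_params <- function(fitspec, theta, dataset) {
  p <- fitspec$fixed
  for (nm in fitspec$free_shared) p[[nm]] <- theta[[nm]]
  for (nm in fitspec$free_per_dataset) {
    key <- paste0(nm, "__", dataset$label)
    if (key %in% names(theta)) p[[nm]] <- theta[[key]]
  }
  if (dataset$condition == "free") p$kappa_mu <- 0
  if (is.null(p$B)) p$B <- dataset$radius[1]
  p
}

model_radii <- function(fitspec, p, dataset) {
  t_hat <- (dataset$time - dataset$time[1]) / p$T
  dp <- dimensionless_params(chat = p$chat, kappa_mu = p$kappa_mu,
                             sigmahat_mu = p$sigmahat_mu, beta = p$beta,
                             B_over_L = p$B / p$L)
  t_end <- max(t_hat)
  if (t_end <= 0) return(rep(p$B, length(t_hat)))
  traj <- simulate_spheroid(dp, fitspec$law, t_end = t_end, dt = fitspec$dt,
                            n = fitspec$n, snapshot_stride = .Machine$integer.max,
                            resolution_warn = 0)
  s <- traj$series
  b_hat <- stats::approx(s$t, s$b, xout = pmin(t_hat, max(s$t)),
                         rule = 2)$y
  b_hat * p$L
}

#' Least-squares objective over growth datasets
#'
#' Sum over datasets and timepoints of squared residuals between observed
#' and simulated radii (or volumes / relative radii, per the fit
#' specification). Model time zero is aligned to each dataset's first
#' observation. Simulation failures contribute a large finite penalty
#' rather than an error.
#'
#' @param theta named numeric vector of free parameter values.
#' @param fitspec a [fit_spec()].
#' @param datasets list of [growth_dataset()] objects.
#' @return Non-negative scalar.
#' @export
growth_objective <- function(theta, fitspec, datasets) {
  stopifnot(inherits(fitspec, "fit_spec"))
  if (inherits(datasets, "growth_dataset")) datasets <- list(datasets)
  sum(vapply(datasets, function(ds) {
    objective_one(theta, fitspec, ds)
  }, 0))
}

objective_one <- function(theta, fitspec, ds) {
  p <- dataset_params(fitspec, theta, ds)
  b_model <- tryCatch(model_radii(fitspec, p, ds), error = function(e) NULL)
  if (is.null(b_model) || any(!is.finite(b_model))) return(1e10)
  res <- switch(fitspec$residual,
                radius = b_model - ds$radius,
                volume = b_model^3 - ds$radius^3,
                relative = (b_model - ds$radius) / ds$radius)
  sum(res^2)
}

# Latin-hypercube starts within bounds (deterministic given the RNG state)
lhs_starts <- function(n_starts, lower, upper) {
  d <- length(lower)
  out <- matrix(0, n_starts, d)
  for (j in seq_len(d)) {
    strata <- (sample.int(n_starts) - 1 + stats::runif(n_starts)) / n_starts
    out[, j] <- lower[j] + strata * (upper[j] - lower[j])
  }
  out
}

to_unbounded <- function(p, lower, upper) {
  u <- pmin(1 - 1e-10, pmax(1e-10, (p - lower) / (upper - lower)))
  stats::qlogis(u)
}
from_unbounded <- function(x, lower, upper) {
  lower + (upper - lower) * stats::plogis(x)
}

#' Fit growth-curve data
#'
#' Bounded derivative-free minimisation of [growth_objective()]:
#' Nelder-Mead simplex on a logistic transform of each free parameter to
#' its bounds, repeated from Latin-hypercube starting points. When all
#' free parameters are per-dataset (no shared free parameters), the
#' objective separates and each dataset is fitted independently, which is
#' both faster and more robust. Deterministic for a given `seed`.
#'
#' @param datasets list of [growth_dataset()] objects (or a single one).
#' @param fitspec a [fit_spec()].
#' @param n_starts number of multistart points (default 16).
#' @param seed integer seed controlling the multistart design.
#' @param maxit,reltol passed to [stats::optim()] (Nelder-Mead).
#' @return Object of class `fit_result`: list with `par` (named best-fit
#'   values), `objective`, `per_dataset_rss`, `convergence` (0 =
#'   converged), `starts` (data frame logging every start and its final
#'   value), and `manifest` (seed, counts, tolerances).
#' @export
fit_growth <- function(datasets, fitspec, n_starts = 16, seed = 1,
                       maxit = 400, reltol = 1e-10) {
  stopifnot(inherits(fitspec, "fit_spec"))
  if (inherits(datasets, "growth_dataset")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1)
  labs <- vapply(datasets, `[[`, "", "label")
  if (anyDuplicated(labs)) stop("dataset labels must be unique", call. = FALSE)

  par_names <- free_param_names(fitspec, datasets)
  if (length(par_names) == 0) {
    rss <- vapply(datasets, function(ds) {
      objective_one(numeric(0), fitspec, ds)
    }, 0)
    return(structure(list(par = numeric(0), objective = sum(rss),
                          per_dataset_rss = stats::setNames(rss, labs),
                          convergence = 0L,
                          starts = data.frame(),
                          manifest = list(seed = seed, n_starts = 0L)),
                     class = "fit_result"))
  }

  separable <- length(fitspec$free_shared) == 0 && length(datasets) > 1
  if (separable) {
    fits <- lapply(datasets, function(ds) {
      fit_growth(list(ds), fitspec, n_starts = n_starts, seed = seed,
                 maxit = maxit, reltol = reltol)
    })
    par <- do.call(c, lapply(fits, `[[`, "par"))
    rss <- vapply(fits, `[[`, 0, "objective")
    return(structure(list(par = par, objective = sum(rss),
                          per_dataset_rss = stats::setNames(rss, labs),
                          convergence = max(vapply(fits, `[[`, 0L,
                                                   "convergence")),
                          starts = do.call(rbind,
                                           lapply(fits, `[[`, "starts")),
                          manifest = list(seed = seed, n_starts = n_starts,
                                          maxit = maxit, reltol = reltol,
                                          separable = TRUE)),
                     class = "fit_result"))
  }

  bnds <- bounds_for(fitspec, par_names)
  obj_t <- function(x) {
    theta <- stats::setNames(from_unbounded(x, bnds$lower, bnds$upper),
                             par_names)
    growth_objective(theta, fitspec, datasets)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  starts <- lhs_starts(n_starts, bnds$lower, bnds$upper)
  runs <- lapply(seq_len(n_starts), function(i) {
    x0 <- to_unbounded(starts[i, ], bnds$lower, bnds$upper)
    stats::optim(x0, obj_t, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = reltol))
  })
  values <- vapply(runs, `[[`, 0, "value")
  best <- runs[[which.min(values)]]
  par <- stats::setNames(from_unbounded(best$par, bnds$lower, bnds$upper),
                         par_names)
  rss <- vapply(datasets, function(ds) objective_one(par, fitspec, ds), 0)
  starts_log <- data.frame(start = seq_len(n_starts), value = values)
  structure(list(par = par, objective = sum(rss),
                 per_dataset_rss = stats::setNames(rss, labs),
                 convergence = best$convergence,
                 starts = starts_log,
                 manifest = list(seed = seed, n_starts = n_starts,
                                 maxit = maxit, reltol = reltol,
                                 separable = FALSE)),
            class = "fit_result")
}

#' Fitted model curves for a fit result
#'
#' @param fit a `fit_result`.
#' @param fitspec the [fit_spec()] used for the fit.
#' @param datasets the fitted datasets.
#' @return Named list of data frames (`time`, `radius_obs`, `radius_fit`).
#' @export
fitted_curves <- function(fit, fitspec, datasets) {
  if (inherits(datasets, "growth_dataset")) datasets <- list(datasets)
  out <- lapply(datasets, function(ds) {
    p <- dataset_params(fitspec, fit$par, ds)
    data.frame(time = ds$time, radius_obs = ds$radius,
               radius_fit = model_radii(fitspec, p, ds))
  })
  stats::setNames(out, vapply(datasets, `[[`, "", "label"))
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> objective = %.6g (convergence %d)\n",
              x$objective, x$convergence))
  if (length(x$par)) print(x$par)
  invisible(x)
}
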