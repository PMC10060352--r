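# Synthetic multi-condition growth curves. The generator emulates the
# structure of classical spheroid-compression experiments: one condition
# in free suspension (kappa = 0) plus several gel-embedded conditions of
# increasing stiffness, each showing the canonical exponential -> linear
# -> saturating radius curve, observed at discrete times with additive
# Gaussian measurement noise.

#' Default multi-condition parameter sets for the synthetic generator
#'
#' One free-suspension condition and three embedded conditions of
#' increasing external stiffness, sharing all biological and mechanical
#' parameters (the combined local/non-local law's defaults: necrosis
#' threshold at a quarter of the surface concentration, stress threshold
#' of one shear modulus, local sensitivity 6.25) and a common initial
#' radius of half a diffusive length.
#'
#' @param kappa_mu stiffnesses of the conditions (units of `mu`); a zero
#'   entry is treated as free suspension.
#' @param B_over_L initial radius (recycled across conditions).
#' @param chat,sigmahat_mu,beta shared biology/mechanics.
#' @return Named list of [dimensionless_params()], names `cond1`, ...
#' @export
synthetic_conditions <- function(kappa_mu = c(0, 0.1, 0.3, 1),
                                 B_over_L = 0.5, chat = 0.25,
                                 sigmahat_mu = -1, beta = 6.25) {
  B_over_L <- rep_len(B_over_L, length(kappa_mu))
  out <- lapply(seq_along(kappa_mu), function(i) {
    dimensionless_params(chat = chat, kappa_mu = kappa_mu[i],
                         sigmahat_mu = sigmahat_mu, beta = beta,
                         B_over_L = B_over_L[i])
  })
  stats::setNames(out, paste0("cond", seq_along(kappa_mu)))
}

#' Generate synthetic growth-curve datasets
#'
#' Simulates each condition with the requested law, samples the outer
#' radius at the observation times and adds independent zero-mean
#' Gaussian noise to the radii. Deterministic for a given seed. Radii are
#' reported in units of `L` and times in units of `T` (scale by the
#' condition's `L` and `T` for dimensional output).
#'
#' @param conditions named list of parameter objects (see
#'   [synthetic_conditions()]); conditions with `kappa = 0` are labelled
#'   free suspension.
#' @param law law id (default `"M5"`).
#' @param times observation times in units of `T` (first entry is the
#'   model's time zero).
#' @param noise_sd standard deviation of additive radius noise (units of
#'   `L`), `>= 0`; default 0.02, about 2% of typical radii.
#' @param seed integer seed.
#' @param dt,n simulator controls (match these in [fit_spec()] when doing
#'   recovery studies so discretisation bias cancels).
#' @return List of [growth_dataset()] objects.
#' @export
synthesize_growth_data <- function(conditions = synthetic_conditions(),
                                   law = "M5",
                                   times = seq(0, 20, by = 1),
                                   noise_sd = 0.02, seed = 1,
                                   dt = 0.05, n = 80) {
  stopifnot(noise_sd >= 0, length(times) >= 1, all(diff(times) > 0))
  if (is.null(names(conditions))) {
    names(conditions) <- paste0("cond", seq_along(conditions))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  lapply(names(conditions), function(nm) {
    dp <- as_dimensionless(conditions[[nm]])
    t_hat <- times - times[1]
    b <- if (max(t_hat) > 0) {
      traj <- simulate_spheroid(dp, law, t_end = max(t_hat), dt = dt, n = n,
                                snapshot_stride = .Machine$integer.max,
                                resolution_warn = 0)
      stats::approx(traj$series$t, traj$series$b,
                    xout = pmin(t_hat, max(traj$series$t)), rule = 2)$y
    } else {
      rep(dp$B_over_L, length(t_hat))
    }
    radius <- b + stats::rnorm(length(b), sd = noise_sd)
    if (any(radius <= 0)) {
      radius <- pmax(radius, 1e-6 * dp$B_over_L)
    }
    growth_dataset(nm, times, radius,
                   condition = if (dp$kappa_mu == 0) "free" else "embedded")
  })
}
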