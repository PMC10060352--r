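# The hierarchy of growth laws. All take the generic form
#   (1/gamma) dgamma/dt = k * f(sigma, c),
# differing in f:
#   M1  nutrient only:              f = c - c_hat
#   M2  + local radial stress:      f = n(sigma_r) (c - c_hat) for c >= c_hat,
#                                   unmodified decay below threshold
#   M3  + permanent necrosis:       f = n(sigma_r) (c - c_hat) outside the
#                                   front, 0 inside (never negative)
#   M4  non-local stress measure:   n evaluated on min over the spheroid of
#                                   both stress components
#   M5  local + non-local:         extra factor n(beta * sigma_r)
#
# With dimensionless parameters, rates are per unit T and concentrations
# in units of c_inf; stresses are in the units of the supplied threshold
# (mu for dimensionless parameters).

#' Growth law selector
#'
#' @param id one of `"M1"` to `"M5"`.
#' @return Object of class `growth_law` (list with `id`).
#' @export
growth_law <- function(id) {
  id <- match.arg(toupper(id), c("M1", "M2", "M3", "M4", "M5"))
  structure(list(id = id), class = "growth_law")
}

#' Piecewise-linear stress modifier
#'
#' The weakly increasing function `n(s)` mapping stress to a growth factor
#' in `[0, 1]`: zero for `s < sigma_hat`, rising linearly as
#' `1 - s / sigma_hat` on `[sigma_hat, 0)`, and one for `s >= 0`.
#' Compression beyond the threshold fully arrests growth; tension has no
#' effect. The degenerate case `sigma_hat = 0` is taken as the pointwise
#' limit: 1 for `s >= 0`, 0 otherwise.
#'
#' @param s stress (any units, consistent with `sigma_hat`); vectorised.
#' @param sigma_hat stress threshold, `<= 0`.
#' @return Values in `[0, 1]`.
#' @export
stress_modifier <- function(s, sigma_hat) {
  if (!is.finite(sigma_hat) || sigma_hat > 0) {
    stop("sigma_hat must be non-positive", call. = FALSE)
  }
  if (sigma_hat == 0) return(as.numeric(s >= 0))
  pmin(1, pmax(0, 1 - s / sigma_hat))
}

# threshold and rate constant appropriate to the parameter class
law_constants <- function(params) {
  if (inherits(params, "spheroid_params")) {
    list(k = params$k, c_hat = params$c_hat,
         sigma_hat = params$sigma_hat / params$mu, beta = params$beta)
  } else {
    stopifnot(inherits(params, "spheroid_dimensionless"))
    list(k = 1, c_hat = params$chat, sigma_hat = params$sigmahat_mu,
         beta = params$beta)
  }
}

#' Growth rates of the five laws
#'
#' Relative growth rates `(1/gamma) dgamma/dt` at given nutrient
#' concentration and stress. Concentrations are in the units of the
#' parameter object (`c_inf` units when dimensionless); stresses are in
#' units of `mu` throughout. Vectorised over nodes.
#'
#' @param c nutrient concentration(s).
#' @param params parameter object of either class.
#' @return Relative rate(s), per unit time (`T` for dimensionless
#'   parameters).
#' @export
growth_rate_m1 <- function(c, params) {
  lc <- law_constants(params)
  lc$k * (c - lc$c_hat)
}

#' @rdname growth_rate_m1
#' @param sigma_r_local local radial stress (units of `mu`).
#' @export
growth_rate_m2 <- function(c, sigma_r_local, params) {
  lc <- law_constants(params)
  n <- stress_modifier(sigma_r_local, lc$sigma_hat)
  lc$k * ifelse(c >= lc$c_hat, n * (c - lc$c_hat), c - lc$c_hat)
}

#' @rdname growth_rate_m1
#' @param R Lagrangian radius (vectorised with `c`).
#' @param R_N current Lagrangian necrotic front.
#' @export
growth_rate_m3 <- function(c, sigma_r_local, R, R_N, params) {
  lc <- law_constants(params)
  n <- stress_modifier(sigma_r_local, lc$sigma_hat)
  # outside the front c >= c_hat up to discretisation; clamp preserves the
  # non-negativity guarantee at finite resolution
  rate <- lc$k * pmax(0, n * (c - lc$c_hat))
  rate[R < R_N] <- 0
  rate
}

#' @rdname growth_rate_m1
#' @param global_measure the non-local stress measure from
#'   [global_stress_measure()] (units of `mu`).
#' @export
growth_rate_m4 <- function(c, global_measure, R, R_N, params) {
  lc <- law_constants(params)
  n <- stress_modifier(global_measure, lc$sigma_hat)
  rate <- lc$k * pmax(0, n * (c - lc$c_hat))
  rate[R < R_N] <- 0
  rate
}

#' @rdname growth_rate_m1
#' @export
growth_rate_m5 <- function(c, global_measure, sigma_r_local, R, R_N, params) {
  lc <- law_constants(params)
  n_global <- stress_modifier(global_measure, lc$sigma_hat)
  n_local <- stress_modifier(lc$beta * sigma_r_local, lc$sigma_hat)
  rate <- lc$k * pmax(0, n_global * n_local * (c - lc$c_hat))
  rate[R < R_N] <- 0
  rate
}

#' Non-local stress measure
#'
#' The most compressive stress experienced anywhere in the spheroid in any
#' direction: the minimum over all nodes of both the radial and hoop
#' stress fields (the two eigenvalue branches of the diagonal Cauchy
#' stress). Loaded stresses enter this measure.
#'
#' @param sigma_r,sigma_theta stress fields on a common grid.
#' @return Scalar stress.
#' @export
global_stress_measure <- function(sigma_r, sigma_theta) {
  stopifnot(length(sigma_r) == length(sigma_theta))
  min(sigma_r, sigma_theta)
}

#' Update the Lagrangian necrotic front
#'
#' The front is the running maximum over time of the Lagrangian preimage
#' of the necrosis threshold radius: necrosis is permanent, so `R_N` never
#' decreases even if the nutrient field later recovers. The preimage is
#' located by inverting the (monotone) current radius map at the
#' closed-form threshold radius, with linear interpolation between
#' bracketing nodes.
#'
#' @param R_N previous front (Lagrangian length).
#' @param state a [spheroid_state()].
#' @param params parameter object of either class (consistent with the
#'   state's length units).
#' @return Updated front, `>= R_N`.
#' @export
update_necrotic_front <- function(R_N, state, params) {
  stopifnot(inherits(state, "spheroid_state"), R_N >= 0)
  b <- state$r[length(state$r)]
  r_star <- necrosis_boundary_radius(b, params)
  if (is.na(r_star)) return(R_N)
  R_star <- stats::approx(state$r, state$grid$R, xout = r_star,
                          ties = "ordered")$y
  max(R_N, R_star)
}
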