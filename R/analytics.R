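# Closed-form results for the nutrient-only model (M1) and robust-model
# bounds. These double as independent oracles for the simulator.

#' Closed-form outer radius under nutrient-only growth
#'
#' The explicit solution of the M1 outer-radius ODE
#' `db/dt = k b (-lam b^2 / (15 D) + c_inf - c_hat)`:
#' a logistic-like interpolation from the initial radius `B` to the stable
#' steady state `b_N* = sqrt(15 D (c_inf - c_hat) / lam)`.
#'
#' @param t time (units of `T` for dimensionless parameters); vectorised.
#' @param params parameter object of either class.
#' @return Outer radius at `t` (units of `L` for dimensionless
#'   parameters).
#' @export
closed_form_radius <- function(t, params) {
  dp <- as_dimensionless(params)
  dimensional <- inherits(params, "spheroid_params")
  t_hat <- if (dimensional) t / dp$T else t
  gap <- 1 - dp$chat                    # (c_inf - c_hat) / c_inf
  bstar <- sqrt(15 * gap)
  B <- dp$B_over_L
  b_hat <- bstar / sqrt(1 + (bstar^2 / B^2 - 1) * exp(-2 * gap * t_hat))
  if (dimensional) b_hat * dp$L else b_hat
}

#' Steady-state geometry of the nutrient-only model
#'
#' The M1 dynamics have two steady outer radii: `b = 0` (linearly
#' unstable) and `b = b_N* = sqrt(15 (c_inf - c_hat) / c_inf) L` (stable).
#' At the nonzero state a necrotic core of radius
#' `r_c = 3 sqrt((c_inf - c_hat) / c_inf) L` sits inside a proliferative
#' rim; the ratio `r_c / b_N* = 3 / sqrt(15)` and hence the necrotic
#' volume fraction `(3 / sqrt(15))^3` (about 46%) are independent of all
#' parameters.
#'
#' @param params parameter object of either class.
#' @return Object of class `steady_state_summary`: list with `b_star`,
#'   `r_necrotic` (units of `L` when dimensionless),
#'   `necrotic_volume_fraction`, and `stability` (named labels for the
#'   zero and nonzero states).
#' @export
steady_state_radius <- function(params) {
  dp <- as_dimensionless(params)
  dimensional <- inherits(params, "spheroid_params")
  L <- if (dimensional) dp$L else 1
  gap <- 1 - dp$chat
  structure(list(
    b_star = sqrt(15 * gap) * L,
    r_necrotic = 3 * sqrt(gap) * L,
    necrotic_volume_fraction = (3 / sqrt(15))^3,
    stability = c(zero = "unstable", nonzero = "stable")
  ), class = "steady_state_summary")
}

#' Upper bound on the spheroid radius under the robust laws
#'
#' For the non-local stress-regulated laws (M4, M5) with a resistive
#' external medium (`kappa > 0`), growth arrests once the compressive
#' boundary stress reaches the threshold: `-kappa (b - B) / B =
#' sigma_hat`, giving `b <= B (1 - sigma_hat / kappa)`. In free
#' suspension (`kappa = 0`) no such bound exists and `Inf` is returned.
#'
#' @param params parameter object of either class.
#' @return Length (units of `L` when dimensionless), or `Inf`.
#' @export
radius_upper_bound <- function(params) {
  dp <- as_dimensionless(params)
  dimensional <- inherits(params, "spheroid_params")
  B <- dp$B_over_L * if (dimensional) dp$L else 1
  if (dp$kappa_mu == 0) return(Inf)
  B * (1 - dp$sigmahat_mu / dp$kappa_mu)
}

#' Late-time growth rate of the boundary hoop stress (M1)
#'
#' Under the nutrient-only law at the steady outer radius, material at the
#' boundary keeps growing exponentially, `gamma(B, t) ~ exp(k (c_inf -
#' c_hat) t)`, so its elastic stretch decays as `alpha(B, t) ~ exp(-k
#' (c_inf - c_hat) t)`. The hoop stress at the boundary is dominated by
#' the `mu * alpha^-4` term of the neo-Hookean response, so `|sigma_theta|`
#' grows exponentially at rate `4 k (c_inf - c_hat)`. This rate is a
#' derived asymptotic constant; the prefactors are not exposed.
#'
#' @param params parameter object of either class.
#' @return Rate (per unit `T` for dimensionless parameters).
#' @export
boundary_stress_rate <- function(params) {
  if (inherits(params, "spheroid_params")) {
    4 * params$k * (params$c_inf - params$c_hat)
  } else {
    stopifnot(inherits(params, "spheroid_dimensionless"))
    4 * (1 - params$chat)
  }
}

#' @export
print.steady_state_summary <- function(x, ...) {
  cat("<steady_state_summary>\n")
  cat(sprintf("  b* = %.6g (stable); b = 0 unstable\n", x$b_star))
  cat(sprintf("  necrotic radius = %.6g (ratio %.6g, volume fraction %.4f)\n",
              x$r_necrotic, x$r_necrotic / x$b_star,
              x$necrotic_volume_fraction))
  invisible(x)
}
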