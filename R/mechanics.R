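# Solid mechanics of the incompressible neo-Hookean spheroid.
#
# Momentum balance reduces to a single quasistatic Lagrangian ODE for the
# radial Cauchy stress,
#   d sigma_r / dR = 2 mu gamma (r^6 - gamma^6 R^6) / r^7,
# integrated inwards from the boundary. The hoop stress follows
# algebraically from sigma_theta = sigma_r + mu (alpha^2 - alpha^-4); the
# equivalent derivative form sigma_theta = sigma_r + (r/2) dsigma_r/dr is
# kept as a test, not used for computation. All stresses are reported in
# units of the shear modulus mu, in which the equations are
# scale-invariant.

stress_integrand <- function(state) {
  R <- state$grid$R
  g <- state$gamma
  r <- state$r
  s <- numeric(length(R))
  # centre: removable singularity; gamma smooth with gamma'(0) = 0 makes
  # the numerator O(R^8) against a denominator O(R^7). gamma^6 is written
  # (gamma^3)^2 to match the simulator's evaluation bit-for-bit.
  s[-1] <- 2 * g[-1] * (r[-1]^6 - (g[-1]^3)^2 * R[-1]^6) / r[-1]^7
  s
}

#' Radial Cauchy stress profile
#'
#' Integrates the radial stress ODE inwards from `R = B`. The `"loaded"`
#' variant uses the compressive external boundary condition
#' `sigma_r(B) = -kappa * (b - B) / B`; the `"residual"` variant uses a
#' traction-free boundary, `sigma_r(B) = 0`, giving the stress that would
#' remain if the external load were removed at this instant.
#'
#' @param state a [spheroid_state()].
#' @param params parameter object of either class (only `kappa / mu` is
#'   used).
#' @param variant `"loaded"` or `"residual"`.
#' @return Object of class `stress_profile`: list with `sigma_r`,
#'   `sigma_theta`, `variant`, `boundary_value` (all stresses in units of
#'   `mu`).
#' @export
radial_stress <- function(state, params, variant = c("loaded", "residual")) {
  stopifnot(inherits(state, "spheroid_state"))
  variant <- match.arg(variant)
  if (any(state$r[-1] <= 0)) {
    stop("current radii must be positive away from the centre", call. = FALSE)
  }
  dp <- as_dimensionless(params)
  R <- state$grid$R
  B <- state$grid$B
  b <- state$r[length(state$r)]
  sigma_B <- if (variant == "loaded") -dp$kappa_mu * (b - B) / B else 0
  I <- cumtrapz(R, stress_integrand(state))
  sigma_r <- sigma_B - (I[length(I)] - I)
  sigma_theta <- hoop_stress(state, sigma_r)
  structure(list(sigma_r = sigma_r, sigma_theta = sigma_theta,
                 variant = variant, boundary_value = sigma_B),
            class = "stress_profile")
}

#' Hoop stress from the radial stress
#'
#' Nodewise algebraic evaluation of
#' `sigma_theta = sigma_r + mu * (alpha^2 - alpha^-4)` (units of `mu`);
#' no numerical differentiation is involved. The difference
#' `sigma_theta - sigma_r` has the sign of `alpha - 1`.
#'
#' @param state a [spheroid_state()].
#' @param sigma_r radial stress at the same nodes (units of `mu`).
#' @return Numeric vector `sigma_theta(R_i)`.
#' @export
hoop_stress <- function(state, sigma_r) {
  stopifnot(inherits(state, "spheroid_state"),
            length(sigma_r) == length(state$grid$R))
  alpha <- elastic_stretch(state)
  sigma_r + (alpha^2 - alpha^(-4))
}

#' Residual stress profiles
#'
#' Radial and hoop components of the residual Cauchy stress (traction-free
#' boundary). Also reports the boundary residual hoop stress and whether
#' it is tensile -- the signature feature that distinguishes the combined
#' local/non-local growth law (M5) from the purely non-local one (M4), for
#' which the boundary residual hoop stress is provably never tensile when
#' the growth stretch is non-decreasing in `R`.
#'
#' @inheritParams radial_stress
#' @return A `stress_profile` (variant `"residual"`) with extra fields
#'   `boundary_hoop` and `tensile_boundary`.
#' @export
residual_profiles <- function(state, params) {
  prof <- radial_stress(state, params, variant = "residual")
  prof$boundary_hoop <- prof$sigma_theta[length(prof$sigma_theta)]
  prof$tensile_boundary <- prof$boundary_hoop > 0
  prof
}

#' Export a stress profile as CSV
#'
#' Columns: `R`, `r`, `sigma_r`, `sigma_theta` (stresses in units of `mu`).
#'
#' @param profile a `stress_profile`.
#' @param state the [spheroid_state()] it was computed from.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stress_csv <- function(profile, state, path) {
  stopifnot(inherits(profile, "stress_profile"),
            inherits(state, "spheroid_state"))
  utils::write.csv(data.frame(R = state$grid$R, r = state$r,
                              sigma_r = profile$sigma_r,
                              sigma_theta = profile$sigma_theta),
                   path, row.names = FALSE)
  invisible(path)
}
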