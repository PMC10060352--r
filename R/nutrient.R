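#' Quasistatic nutrient profile
#'
#' The steady, radially symmetric solution of the nutrient
#' reaction--diffusion balance with constant consumption,
#' `c(r) = lam * (r^2 - b^2) / (6 D) + c_inf`, subject to `c(b) = c_inf`
#' and no flux at the centre. Diffusion is taken quasistatic relative to
#' growth, so the profile depends on time only through the outer radius
#' `b`.
#'
#' For spheroids larger than the depletion radius [depletion_radius()] the
#' parabolic profile predicts negative concentrations at the core. The
#' profile is nevertheless returned unmodified (the model's stated
#' simplification), with a warning and a `valid = FALSE` flag; set
#' `strict = TRUE` to turn this into an error.
#'
#' @param r numeric vector of Eulerian radii in `[0, b]`.
#' @param b outer radius of the spheroid, `>= 0`.
#' @param params a [spheroid_params()] or [dimensionless_params()] object.
#'   With dimensionless parameters, `r` and `b` are in units of `L` and the
#'   returned concentrations in units of `c_inf`.
#' @param strict error (rather than warn) when `b` exceeds the depletion
#'   radius.
#' @return An object of class `nutrient_field`: list with elements `r`,
#'   `values`, `b`, `valid`.
#' @export
nutrient_profile <- function(r, b, params, strict = FALSE) {
  if (any(r < 0) || any(r > b * (1 + 1e-12))) {
    stop("radii must lie in [0, b]", call. = FALSE)
  }
  if (inherits(params, "spheroid_params")) {
    values <- params$lam * (r^2 - b^2) / (6 * params$D) + params$c_inf
  } else {
    stopifnot(inherits(params, "spheroid_dimensionless"))
    values <- (r^2 - b^2) / 6 + 1
  }
  valid <- b <= depletion_radius(params) * (1 + 1e-12)
  if (!valid) {
    msg <- "spheroid exceeds the nutrient depletion radius; profile is negative at the core"
    if (strict) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  structure(list(r = r, values = values, b = b, valid = valid),
            class = "nutrient_field")
}

#' Nutrient depletion radius
#'
#' The spheroid radius at which the parabolic nutrient profile first
#' vanishes at the centre: `sqrt(6 D c_inf / lam) = sqrt(6) * L`.
#'
#' @inheritParams nutrient_profile
#' @return Length (units of `L` for dimensionless parameters).
#' @export
depletion_radius <- function(params) {
  if (inherits(params, "spheroid_params")) {
    sqrt(6 * params$D * params$c_inf / params$lam)
  } else {
    stopifnot(inherits(params, "spheroid_dimensionless"))
    sqrt(6)
  }
}

#' Eulerian radius of the necrosis threshold
#'
#' The unique radius `r*` at which the nutrient profile crosses the
#' necrosis threshold `c_hat`, in closed form
#' `r* = sqrt(b^2 - 6 D (c_inf - c_hat) / lam)`. Returns `NA` when the
#' centre concentration is at or above the threshold (fully perfused
#' spheroid).
#'
#' @inheritParams nutrient_profile
#' @return Length, or `NA_real_`.
#' @export
necrosis_boundary_radius <- function(b, params) {
  stopifnot(b >= 0)
  if (inherits(params, "spheroid_params")) {
    gap <- 6 * params$D * (params$c_inf - params$c_hat) / params$lam
  } else {
    stopifnot(inherits(params, "spheroid_dimensionless"))
    gap <- 6 * (1 - params$chat)
  }
  if (b^2 <= gap) return(NA_real_)
  sqrt(b^2 - gap)
}

#' Export a nutrient field as a two-column CSV
#'
#' @param field a `nutrient_field` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_nutrient_csv <- function(field, path) {
  stopifnot(inherits(field, "nutrient_field"))
  utils::write.csv(data.frame(r = field$r, c = field$values), path,
                   row.names = FALSE)
  invisible(path)
}
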