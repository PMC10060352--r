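#' Dimensional model parameters
#'
#' Construct and validate the full set of dimensional parameters for the
#' morphoelastic spheroid models. Units are documented conventions, not
#' enforced: any consistent system (e.g. micrometres, days, kilopascals,
#' millimolar) may be used.
#'
#' @param k growth-rate constant (1 / (concentration x time)), `> 0`.
#' @param c_inf nutrient concentration at the spheroid surface (concentration),
#'   `> 0`.
#' @param c_hat necrosis threshold concentration, with `0 < c_hat < c_inf`.
#' @param lam constant nutrient consumption rate (concentration / time), `> 0`.
#' @param D nutrient diffusivity (length^2 / time), `> 0`.
#' @param mu shear modulus of the (neo-Hookean, incompressible) tissue
#'   (stress), `> 0`.
#' @param kappa stiffness of the surrounding medium (stress), `>= 0`;
#'   `kappa = 0` is growth in free suspension.
#' @param sigma_hat radial-stress threshold below which growth is fully
#'   arrested (stress), `<= 0`.
#' @param beta sensitivity multiplier of the local stress response relative
#'   to the global one (dimensionless), `> 0`; only used by model M5.
#' @param B initial spheroid radius (length), `> 0`.
#'
#' @return An object of class `spheroid_params`.
#' @seealso [dimensionless_params()], [as_dimensionless()],
#'   [diffusive_scales()], [figure_params()]
#' @export
#' @examples
#' p <- spheroid_params(c_hat = 0.8)
#' diffusive_scales(p)
spheroid_params <- function(k = 1, c_inf = 1, c_hat = 0.5, lam = 1, D = 1,
                            mu = 1, kappa = 0, sigma_hat = 0, beta = 1,
                            B = 1) {
  p <- list(k = k, c_inf = c_inf, c_hat = c_hat, lam = lam, D = D, mu = mu,
            kappa = kappa, sigma_hat = sigma_hat, beta = beta, B = B)
  p <- lapply(p, as.numeric)
  class(p) <- "spheroid_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  scalar_finite <- function(x) length(x) == 1L && is.finite(x)
  for (nm in names(p)) {
    if (!scalar_finite(p[[nm]])) {
      stop("parameter '", nm, "' must be a finite scalar", call. = FALSE)
    }
  }
  if (p$k <= 0) stop("k must be positive", call. = FALSE)
  if (p$c_inf <= 0) stop("c_inf must be positive", call. = FALSE)
  if (p$lam <= 0) stop("lam must be positive", call. = FALSE)
  if (p$D <= 0) stop("D must be positive", call. = FALSE)
  if (p$mu <= 0) stop("mu must be positive", call. = FALSE)
  if (p$B <= 0) stop("B must be positive", call. = FALSE)
  if (p$beta <= 0) stop("beta must be positive", call. = FALSE)
  if (p$kappa < 0) stop("kappa must be non-negative", call. = FALSE)
  if (p$sigma_hat > 0) stop("sigma_hat must be non-positive", call. = FALSE)
  if (p$c_hat <= 0 || p$c_hat >= p$c_inf) {
    stop("c_hat must satisfy 0 < c_hat < c_inf", call. = FALSE)
  }
  invisible(p)
}

#' Dimensionless model parameters
#'
#' The reduced parameter set that fully determines the dimensionless
#' dynamics: every simulation in this package is run in units of the
#' diffusive lengthscale `L`, the growth timescale `T`, the shear modulus
#' `mu` and the surface concentration `c_inf`.
#'
#' @param chat necrosis threshold as a fraction of the surface concentration,
#'   in `(0, 1)`.
#' @param kappa_mu external stiffness over shear modulus, `>= 0`.
#' @param sigmahat_mu stress threshold over shear modulus, `<= 0`.
#' @param beta local stress-sensitivity multiplier, `> 0`.
#' @param B_over_L initial radius in units of `L`, `> 0`.
#' @param L,T reference scales (length, time) retained so that dimensional
#'   output can be reconstructed; default 1.
#' @param mu reference stress scale, default 1.
#'
#' @return An object of class `spheroid_dimensionless`.
#' @export
dimensionless_params <- function(chat, kappa_mu = 0, sigmahat_mu = 0,
                                 beta = 1, B_over_L = 1, L = 1, T = 1,
                                 mu = 1) {
  p <- list(chat = as.numeric(chat), kappa_mu = as.numeric(kappa_mu),
            sigmahat_mu = as.numeric(sigmahat_mu), beta = as.numeric(beta),
            B_over_L = as.numeric(B_over_L), L = as.numeric(L),
            T = as.numeric(T), mu = as.numeric(mu))
  class(p) <- "spheroid_dimensionless"
  if (!is.finite(p$chat) || p$chat <= 0 || p$chat >= 1) {
    stop("chat must lie in (0, 1)", call. = FALSE)
  }
  if (p$kappa_mu < 0) stop("kappa_mu must be non-negative", call. = FALSE)
  if (p$sigmahat_mu > 0) stop("sigmahat_mu must be non-positive", call. = FALSE)
  if (p$beta <= 0) stop("beta must be positive", call. = FALSE)
  if (p$B_over_L <= 0) stop("B_over_L must be positive", call. = FALSE)
  if (p$L <= 0 || p$T <= 0 || p$mu <= 0) {
    stop("reference scales L, T, mu must be positive", call. = FALSE)
  }
  p
}

#' Diffusive length- and timescales
#'
#' The natural scales of the spheroid problem: `L = sqrt(D * c_inf / lam)`
#' balances nutrient supply against consumption, and `T = 1 / (k * c_inf)`
#' is the growth timescale at full nutrient availability.
#'
#' @param params a [spheroid_params()] object.
#' @return Named numeric vector with components `L` and `T`.
#' @export
diffusive_scales <- function(params) {
  stopifnot(inherits(params, "spheroid_params"))
  validate_params(params)
  c(L = sqrt(params$D * params$c_inf / params$lam),
    T = 1 / (params$k * params$c_inf))
}

#' Convert parameters to dimensionless form
#'
#' @param params a [spheroid_params()] or [dimensionless_params()] object
#'   (the latter is returned unchanged).
#' @return A [dimensionless_params()] object carrying the reference scales
#'   `L`, `T`, `mu` so the conversion can be inverted by
#'   [dimensional_params()].
#' @export
as_dimensionless <- function(params) {
  if (inherits(params, "spheroid_dimensionless")) return(params)
  stopifnot(inherits(params, "spheroid_params"))
  sc <- diffusive_scales(params)
  dimensionless_params(chat = params$c_hat / params$c_inf,
                       kappa_mu = params$kappa / params$mu,
                       sigmahat_mu = params$sigma_hat / params$mu,
                       beta = params$beta,
                       B_over_L = params$B / sc[["L"]],
                       L = sc[["L"]], T = sc[["T"]], mu = params$mu)
}

#' Reconstruct dimensional parameters from dimensionless ones
#'
#' Inverts [as_dimensionless()] given reference scales. The decomposition of
#' `L` and `T` into `(k, c_inf, lam, D)` is not unique; `c_inf` and `D` must
#' be supplied (defaulting to 1) and `k`, `lam` are solved for.
#'
#' @param dp a [dimensionless_params()] object.
#' @param c_inf,D reference surface concentration and diffusivity.
#' @return A [spheroid_params()] object.
#' @export
dimensional_params <- function(dp, c_inf = 1, D = 1) {
  stopifnot(inherits(dp, "spheroid_dimensionless"))
  lam <- D * c_inf / dp$L^2
  k <- 1 / (dp$T * c_inf)
  spheroid_params(k = k, c_inf = c_inf, c_hat = dp$chat * c_inf, lam = lam,
                  D = D, mu = dp$mu, kappa = dp$kappa_mu * dp$mu,
                  sigma_hat = dp$sigmahat_mu * dp$mu, beta = dp$beta,
                  B = dp$B_over_L * dp$L)
}

#' Named parameter sets for the package's illustrative figures
#'
#' A small registry of dimensionless parameter fixtures spanning the
#' behaviours of the model hierarchy: nutrient-limited saturation
#' (`"fig3"`), local stress limitation with runaway interior stress
#' (`"fig5_text"`, `"fig5_caption"` -- two published values of the external
#' stiffness exist for this illustration, and both are kept), persistent
#' necrosis with stress-driven arrest (`"fig6"`), unbounded evolution under
#' a local law (`"fig7"`), and combined local/non-local stress response
#' with tensile boundary residual hoop stress (`"fig9"`).
#'
#' @param name one of `"fig3"`, `"fig5_text"`, `"fig5_caption"`, `"fig6"`,
#'   `"fig7"`, `"fig9"`. Missing: returns the list of available names.
#' @return A [dimensionless_params()] object, or a character vector of
#'   fixture names.
#' @export
figure_params <- function(name) {
  registry <- list(
    fig3 = list(chat = 4 / 5, kappa_mu = 0, sigmahat_mu = 0, beta = 1,
                B_over_L = 1),
    fig5_text = list(chat = 4 / 5, kappa_mu = 100, sigmahat_mu = -100,
                     beta = 1, B_over_L = 1),
    fig5_caption = list(chat = 4 / 5, kappa_mu = 316.2, sigmahat_mu = -100,
                        beta = 1, B_over_L = 1),
    fig6 = list(chat = 9 / 10, kappa_mu = 1, sigmahat_mu = -100, beta = 1,
                B_over_L = 1 / 100),
    fig7 = list(chat = 4 / 5, kappa_mu = 102.4, sigmahat_mu = -100, beta = 1,
                B_over_L = 1),
    fig9 = list(chat = 1 / 4, kappa_mu = 0.1, sigmahat_mu = -1, beta = 6.25,
                B_over_L = 1)
  )
  if (missing(name)) return(names(registry))
  name <- match.arg(name, names(registry))
  do.call(dimensionless_params, registry[[name]])
}

#' Read / write flat key-value parameter configuration files
#'
#' The configuration format is one `key = value` pair per line, keys being
#' the field names of [spheroid_params()] (dimensional) or
#' [dimensionless_params()] (dimensionless form, detected by the presence
#' of a `chat` key). Blank lines and lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return `read_params_config()` returns a parameter object;
#'   `write_params_config()` returns `path` invisibly.
#' @export
read_params_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) {
    stop("malformed config line: '", lines[which(bad)[1]], "'", call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[[`, "", 2L))))
  if (anyNA(vals)) {
    stop("non-numeric value for key '", keys[which(is.na(vals))[1]], "'",
         call. = FALSE)
  }
  args <- as.list(vals)
  names(args) <- keys
  if ("chat" %in% keys) do.call(dimensionless_params, args)
  else do.call(spheroid_params, args)
}

#' @rdname read_params_config
#' @param params a parameter object of either class.
#' @export
write_params_config <- function(params, path) {
  stopifnot(inherits(params, "spheroid_params") ||
              inherits(params, "spheroid_dimensionless"))
  vals <- unclass(params)
  writeLines(sprintf("%s = %.17g", names(vals), unlist(vals)), path)
  invisible(path)
}

#' Serialise parameters to JSON
#'
#' @param params a parameter object of either class.
#' @return A JSON string (class `json`).
#' @export
params_to_json <- function(params) {
  stopifnot(inherits(params, "spheroid_params") ||
              inherits(params, "spheroid_dimensionless"))
  jsonlite::toJSON(c(list(class = class(params)), unclass(params)),
                   auto_unbox = TRUE, digits = NA)
}

#' @export
print.spheroid_params <- function(x, ...) {
  cat("<spheroid_params>\n")
  print(unlist(unclass(x)))
  sc <- diffusive_scales(x)
  cat(sprintf("derived scales: L = %.6g, T = %.6g\n", sc[["L"]], sc[["T"]]))
  invisible(x)
}

#' @export
print.spheroid_dimensionless <- function(x, ...) {
  cat("<spheroid_dimensionless>\n")
  print(unlist(unclass(x)))
  invisible(x)
}
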