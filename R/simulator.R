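# Time integration of the coupled quasistatic system. The only evolving
# unknowns are the growth-stretch field gamma(R) and the necrotic front
# R_N: radii, nutrient and stresses are recomputed from gamma at every
# evaluation (quasistatic closure). gamma is advanced in log by classical
# 4-stage Runge-Kutta, which keeps it positive by construction.
#
# All computation here is dimensionless: lengths in L, times in T,
# stresses in mu, concentrations in c_inf. Dimensional parameter sets are
# converted at the boundary and the scales stored on the trajectory.

# geometry precomputation shared by all field evaluations
sim_geometry <- function(grid) {
  R <- grid$R
  list(R = R, R2 = R^2, R6 = R^6, B = grid$B, n = length(R))
}

# quasistatic fields from a growth-stretch vector (dimensionless)
sim_fields <- function(gamma, geom, dp) {
  g3 <- gamma^3
  n <- geom$n
  r <- (3 * cum_growth_integral(geom$R, g3))^(1 / 3)
  b <- r[n]
  conc <- (r^2 - b^2) / 6 + 1
  alpha <- r / (geom$R * gamma)
  alpha[1] <- 1
  s <- numeric(n)
  s[-1] <- 2 * gamma[-1] * (r[-1]^6 - g3[-1]^2 * geom$R6[-1]) / r[-1]^7
  I <- c(0, cumsum(0.5 * diff(geom$R) * (s[-1] + s[-n])))
  sigma_B <- -dp$kappa_mu * (b - geom$B) / geom$B
  sigma_r <- sigma_B - (I[n] - I)
  sigma_theta <- sigma_r + (alpha^2 - alpha^(-4))
  list(r = r, b = b, c = conc, alpha = alpha, sigma_r = sigma_r,
       sigma_theta = sigma_theta)
}

# relative growth rates for a law id given fields (dimensionless)
sim_rates <- function(law_id, fields, geom, R_N, dp) {
  switch(law_id,
    M1 = fields$c - dp$chat,
    M2 = {
      n_loc <- stress_modifier(fields$sigma_r, dp$sigmahat_mu)
      ifelse(fields$c >= dp$chat, n_loc * (fields$c - dp$chat),
             fields$c - dp$chat)
    },
    M3 = {
      n_loc <- stress_modifier(fields$sigma_r, dp$sigmahat_mu)
      rate <- pmax(0, n_loc * (fields$c - dp$chat))
      rate[geom$R < R_N] <- 0
      rate
    },
    M4 = {
      m <- min(fields$sigma_r, fields$sigma_theta)
      rate <- pmax(0, stress_modifier(m, dp$sigmahat_mu) *
                     (fields$c - dp$chat))
      rate[geom$R < R_N] <- 0
      rate
    },
    M5 = {
      m <- min(fields$sigma_r, fields$sigma_theta)
      n_glob <- stress_modifier(m, dp$sigmahat_mu)
      n_loc <- stress_modifier(dp$beta * fields$sigma_r, dp$sigmahat_mu)
      rate <- pmax(0, n_glob * n_loc * (fields$c - dp$chat))
      rate[geom$R < R_N] <- 0
      rate
    },
    stop("unknown growth law '", law_id, "'", call. = FALSE))
}

# one RK4 step on log(gamma); R_N frozen during the step
sim_rk4 <- function(y, law_id, geom, R_N, dp, dt) {
  rate_of <- function(yv) {
    sim_rates(law_id, sim_fields(exp(yv), geom, dp), geom, R_N, dp)
  }
  k1 <- rate_of(y)
  k2 <- rate_of(y + 0.5 * dt * k1)
  k3 <- rate_of(y + 0.5 * dt * k2)
  k4 <- rate_of(y + dt * k3)
  y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

integration_error <- function(msg, state) {
  cond <- structure(class = c("morphospheroid_integration_error", "error",
                              "condition"),
                    list(message = msg, call = NULL, last_state = state))
  stop(cond)
}

#' Advance a spheroid state by one time step
#'
#' One classical Runge-Kutta step on the log growth stretch, with the
#' quasistatic fields (current radii, nutrient, loaded stresses)
#' recomputed at every stage. For the history-dependent laws (M3-M5) the
#' necrotic front is updated after the step.
#'
#' The state must be expressed in dimensionless units (lengths in `L`,
#' `dt` in units of `T`).
#'
#' @param state a [spheroid_state()].
#' @param law a [growth_law()] or a law id string.
#' @param params parameter object (converted to dimensionless form).
#' @param dt time step, `> 0`.
#' @return The advanced [spheroid_state()].
#' @export
spheroid_step <- function(state, law, params, dt) {
  stopifnot(inherits(state, "spheroid_state"), dt > 0)
  if (!inherits(law, "growth_law")) law <- growth_law(law)
  dp <- as_dimensionless(params)
  geom <- list(R = state$grid$R, R2 = state$grid$R^2, R6 = state$grid$R^6,
               B = state$grid$B, n = length(state$grid$R))
  y <- sim_rk4(log(state$gamma), law$id, geom, state$R_N, dp, dt)
  if (any(!is.finite(y))) {
    integration_error("non-finite growth stretch encountered", state)
  }
  new_state <- spheroid_state(state$grid, exp(y), t = state$t + dt,
                              R_N = state$R_N)
  if (law$id %in% c("M3", "M4", "M5")) {
    new_state$R_N <- update_necrotic_front(state$R_N, new_state, dp)
  }
  new_state
}

#' Simulate spheroid growth
#'
#' Advances the coupled quasistatic system under a chosen growth law with
#' a fixed time step, recording the outer radius, diagnostics and periodic
#' state snapshots. Terminates early when the outer radius is steady
#' (relative change below `steady_tol` per unit `T` over `steady_window`
#' consecutive steps) or when the growth stretch exceeds `gamma_max` (the
#' unbounded-growth regime of the nutrient-only laws; flagged, not an
#' error).
#'
#' @param params a [spheroid_params()] or [dimensionless_params()] object.
#' @param law a [growth_law()] or law id (`"M1"`..`"M5"`).
#' @param t_end simulation horizon in units of `T`, `> 0`.
#' @param dt time step in units of `T` (default `1/200`).
#' @param n number of Lagrangian grid intervals (default 400).
#' @param grid optional explicit [spheroid_grid()] (must span `[0, B/L]`);
#'   by default a boundary-graded grid with `n` intervals is built (see
#'   [spheroid_grid()] for why grading is needed).
#' @param snapshot_stride store a state snapshot every this many steps;
#'   default chosen to keep about 200 snapshots.
#' @param steady_tol steady-state tolerance on the relative rate of change
#'   of `b` (per unit `T`); default `1e-8`.
#' @param steady_window consecutive below-tolerance steps required.
#' @param gamma_max overflow guard on the growth stretch.
#' @param quiescent_tol maximum nodal relative growth rate below which the
#'   final state is flagged quiescent.
#' @param resolution_warn positive to warn (once) when the growth-stretch
#'   boundary layer becomes under-resolved (growth stretch jumping by more
#'   than a factor 3 across the outermost grid interval); `0` disables.
#' @return Object of class `spheroid_trajectory`: list with
#'   * `series`: data frame of `t`, `b`, `sigma_r_centre`,
#'     `global_measure`, `r_necrotic` (all dimensionless);
#'   * `snapshots`: list of stored states (with times and fronts);
#'   * `status`: `"completed"`, `"steady"` or `"unbounded_growth_stretch"`;
#'   * `quiescent`: logical;
#'   * `law`, `params` (dimensionless), `controls`.
#' @export
simulate_spheroid <- function(params, law, t_end, dt = 1 / 200, n = 400,
                              grid = NULL, snapshot_stride = NULL,
                              steady_tol = 1e-8, steady_window = 10,
                              gamma_max = 1e12, quiescent_tol = 1e-10,
                              resolution_warn = 1e-10) {
  stopifnot(t_end > 0, dt > 0, n >= 2)
  if (!inherits(law, "growth_law")) law <- growth_law(law)
  dp <- as_dimensionless(params)
  if (is.null(grid)) grid <- spheroid_grid(dp$B_over_L, n = n)
  stopifnot(inherits(grid, "lagrangian_grid"),
            abs(grid$B - dp$B_over_L) < 1e-12 * dp$B_over_L)
  n_steps <- max(1L, ceiling(t_end / dt))
  if (is.null(snapshot_stride)) {
    snapshot_stride <- max(1L, floor(n_steps / 200))
  }
  geom <- sim_geometry(grid)
  y <- numeric(geom$n)          # log gamma
  R_N <- 0
  uses_front <- law$id %in% c("M3", "M4", "M5")

  t_rec <- numeric(n_steps + 1L)
  b_rec <- numeric(n_steps + 1L)
  s0_rec <- numeric(n_steps + 1L)
  gm_rec <- numeric(n_steps + 1L)
  rn_rec <- numeric(n_steps + 1L)
  snapshots <- vector("list", floor(n_steps / snapshot_stride) + 1L)
  n_snap <- 0L

  record <- function(j, fields, gamma) {
    t_rec[j] <<- (j - 1L) * dt
    b_rec[j] <<- fields$b
    s0_rec[j] <<- fields$sigma_r[1]
    gm_rec[j] <<- min(fields$sigma_r, fields$sigma_theta)
    rn_rec[j] <<- if (uses_front) {
      if (R_N > 0) stats::approx(geom$R, fields$r, xout = R_N)$y else 0
    } else {
      r_star <- necrosis_boundary_radius(fields$b, dp)
      if (is.na(r_star)) 0 else r_star
    }
  }
  take_snapshot <- function(j, gamma) {
    n_snap <<- n_snap + 1L
    snapshots[[n_snap]] <<- list(t = (j - 1L) * dt, gamma = gamma, R_N = R_N)
  }

  fields <- sim_fields(exp(y), geom, dp)
  record(1L, fields, exp(y))
  take_snapshot(1L, exp(y))

  status <- "completed"
  below <- 0L
  j_last <- n_steps + 1L
  warned_resolution <- FALSE
  for (j in seq_len(n_steps)) {
    y_new <- sim_rk4(y, law$id, geom, R_N, dp, dt)
    if (any(!is.finite(y_new))) {
      integration_error(
        sprintf("non-finite growth stretch encountered at t = %g",
                (j - 1L) * dt),
        spheroid_state(grid, exp(y), t = (j - 1L) * dt, R_N = R_N))
    }
    y <- y_new
    gamma <- exp(y)
    fields <- sim_fields(gamma, geom, dp)
    if (uses_front) {
      r_star <- necrosis_boundary_radius(fields$b, dp)
      if (!is.na(r_star)) {
        R_star <- stats::approx(fields$r, geom$R, xout = r_star,
                                ties = "ordered")$y
        R_N <- max(R_N, R_star)
      }
    }
    record(j + 1L, fields, gamma)
    if (j %% snapshot_stride == 0L) {
      take_snapshot(j + 1L, gamma)
      if (resolution_warn > 0 && !warned_resolution) {
        # the failure mode is an under-resolved boundary layer: the growth
        # stretch should vary gently across the outermost grid interval
        if (gamma[geom$n] / gamma[geom$n - 1L] > 3) {
          warning("growth-stretch boundary layer is under-resolved; ",
                  "decrease the grid's delta_rel or increase n",
                  call. = FALSE)
          warned_resolution <- TRUE
        }
      }
    }
    if (max(gamma) > gamma_max) {
      status <- "unbounded_growth_stretch"
      j_last <- j + 1L
      break
    }
    rel_rate <- abs(b_rec[j + 1L] - b_rec[j]) / (b_rec[j] * dt)
    below <- if (rel_rate < steady_tol) below + 1L else 0L
    if (below >= steady_window) {
      status <- "steady"
      j_last <- j + 1L
      break
    }
  }
  if (j_last == n_steps + 1L && snapshots_missing_final(snapshots, n_snap,
                                                        n_steps * dt)) {
    take_snapshot(n_steps + 1L, exp(y))
  } else if (j_last <= n_steps &&
             snapshots_missing_final(snapshots, n_snap, (j_last - 1L) * dt)) {
    take_snapshot(j_last, exp(y))
  }

  idx <- seq_len(j_last)
  final_rates <- sim_rates(law$id, fields, geom, R_N, dp)
  structure(list(
    series = data.frame(t = t_rec[idx], b = b_rec[idx],
                        sigma_r_centre = s0_rec[idx],
                        global_measure = gm_rec[idx],
                        r_necrotic = rn_rec[idx]),
    snapshots = snapshots[seq_len(n_snap)],
    status = status,
    quiescent = max(abs(final_rates)) < quiescent_tol,
    law = law$id,
    params = dp,
    controls = list(t_end = t_end, dt = dt, n = n,
                    snapshot_stride = snapshot_stride,
                    steady_tol = steady_tol, steady_window = steady_window,
                    gamma_max = gamma_max),
    grid_R = geom$R
  ), class = "spheroid_trajectory")
}

snapshots_missing_final <- function(snapshots, n_snap, t_final) {
  n_snap == 0L || abs(snapshots[[n_snap]]$t - t_final) > 1e-12
}

#' Reconstruct a full state from a stored snapshot
#'
#' @param trajectory a [simulate_spheroid()] result.
#' @param i snapshot index (default: last).
#' @return A [spheroid_state()] in dimensionless units.
#' @export
state_at <- function(trajectory, i = length(trajectory$snapshots)) {
  stopifnot(inherits(trajectory, "spheroid_trajectory"),
            i >= 1, i <= length(trajectory$snapshots))
  snap <- trajectory$snapshots[[i]]
  grid <- spheroid_grid(trajectory$params$B_over_L,
                        nodes = trajectory$grid_R)
  spheroid_state(grid, snap$gamma, t = snap$t, R_N = snap$R_N)
}

#' Eulerian paths of material points
#'
#' Tracks the current radius `r(R, t)` of chosen Lagrangian points across
#' the stored snapshots. Under the nutrient-only law at the steady outer
#' radius, all interior paths drift toward the centre (material turnover).
#'
#' @param trajectory a [simulate_spheroid()] result (with snapshots).
#' @param R_values Lagrangian radii in `[0, B]` (dimensionless units).
#' @return Data frame with column `t` and one column per requested `R`.
#' @export
material_paths <- function(trajectory, R_values) {
  stopifnot(inherits(trajectory, "spheroid_trajectory"),
            length(trajectory$snapshots) > 0)
  B <- trajectory$params$B_over_L
  if (any(R_values < 0) || any(R_values > B * (1 + 1e-12))) {
    stop("R_values must lie in [0, B]", call. = FALSE)
  }
  grid_R <- trajectory$grid_R
  rows <- lapply(trajectory$snapshots, function(snap) {
    r <- (3 * cum_growth_integral(grid_R, snap$gamma^3))^(1 / 3)
    c(snap$t, stats::approx(grid_R, r, xout = R_values)$y)
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("t", paste0("R_", signif(R_values, 6)))
  out
}

#' Boundary hoop-stress history
#'
#' Recomputes the loaded stress fields at every stored snapshot and
#' returns the hoop (and radial) stress at the outer boundary. Under the
#' nutrient-only law at steady outer radius, the boundary hoop stress
#' eventually becomes compressive with magnitude growing exponentially at
#' rate `4 k (c_inf - c_hat)` (see [boundary_stress_rate()]).
#'
#' @param trajectory a [simulate_spheroid()] result (with snapshots).
#' @return Data frame with columns `t`, `sigma_theta_b`, `sigma_r_b`
#'   (units of `mu`).
#' @export
boundary_stress_history <- function(trajectory) {
  stopifnot(inherits(trajectory, "spheroid_trajectory"),
            length(trajectory$snapshots) > 0)
  dp <- trajectory$params
  geom <- sim_geometry(list(R = trajectory$grid_R, B = dp$B_over_L))
  rows <- lapply(trajectory$snapshots, function(snap) {
    f <- sim_fields(snap$gamma, geom, dp)
    c(snap$t, f$sigma_theta[geom$n], f$sigma_r[geom$n])
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("t", "sigma_theta_b", "sigma_r_b")
  out
}

#' @export
print.spheroid_trajectory <- function(x, ...) {
  s <- x$series
  cat(sprintf(
    "<spheroid_trajectory> law %s, %d steps, t in [0, %.4g] T\n",
    x$law, nrow(s) - 1L, s$t[nrow(s)]))
  cat(sprintf("  b/L: %.6g -> %.6g; status: %s%s\n", s$b[1], s$b[nrow(s)],
              x$status, if (x$quiescent) " (quiescent)" else ""))
  invisible(x)
}
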