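#' Repair flux as a function of the damage load
#'
#' The repair term `r(D) = k2 * R * sin(D / R)` for damage `D` in `[0, 1]`
#' and repair capacity `R >= 1/pi`. For small damage loads the flux is
#' approximately `k2 * D`; how strongly it saturates or declines towards high
#' damage loads is set by the capacity. `R = Inf` is the unlimited-capacity
#' sentinel and returns exactly `k2 * D` (the analytic limit). At the lowest
#' admissible capacity, `R = 1/pi`, the effective repair rate drops to zero as
#' the damage load approaches 1.
#'
#' @param D Damage level(s) in `[0, 1]`.
#' @param k2 Repair rate, >= 0.
#' @param R Repair capacity in `[1/pi, Inf]`.
#' @return Repair flux, same length as `D`; non-negative on the domain.
#' @examples
#' repair_rate(0.5, k2 = 0.138, R = 1 / pi)  # peak of the declining profile
#' repair_rate(0.3, k2 = 0.092, R = Inf)     # linear repair, 0.092 * 0.3
#' @export
repair_rate <- function(D, k2, R) {
  if (any(D < 0 | D > 1)) stop("D must lie in [0, 1]")
  if (k2 < 0) stop("k2 must be >= 0")
  if (R < 1 / pi) stop("repair capacity R must be >= 1/pi")
  if (!is.finite(R)) return(k2 * D)
  k2 * R * sin(D / R)
}

#' Time derivatives of the single-cell state
#'
#' Right-hand side of the non-dimensional protein dynamics:
#' `dP/dt = g*P*(1 - S) - k1*P + r(D)` and `dD/dt = k1*P - r(D)`, with size
#' `S = P + Q*D` and repair flux `r(D)` from [repair_rate()]. Damage formation
#' and repair only move mass between the functional and damaged pools, so
#' `dP/dt + dD/dt = g*P*(1 - S)`: growth is slowed (and eventually reversed)
#' by the damage load through `S`.
#'
#' @param state A `cell_state` (or list with `P`, `D`).
#' @param params A `cell_params` object.
#' @return Named numeric vector `c(dP, dD)`.
#' @export
ode_rhs <- function(state, params) {
  r <- repair_rate(state$D, params$k2, params$R)
  S <- state$P + params$Q * state$D
  dP <- params$g * state$P * (1 - S) - params$k1 * state$P + r
  dD <- params$k1 * state$P - r
  c(dP = dP, dD = dD)
}

# parameter vector in the order the compiled code expects
.parms_vec <- function(params) {
  c(params$g, params$k1, params$k2, params$Q, params$R,
    params$P_div, params$D_death, params$D_health)
}

# One lsodar leg from (t0, y) to the first root or t_max, using the compiled
# derivatives. Returns list(t, y, root = 0 (none) | index of root fired,
# traj = dense output matrix or NULL).
.integrate_leg <- function(y, t0, t_max, params, dense_dt = NULL,
                           rtol = 1e-10, atol = 1e-12) {
  times <- if (is.null(dense_dt)) c(t0, t_max) else
    unique(c(seq(t0, t_max, by = dense_dt), t_max))
  out <- deSolve::lsodar(y = y, times = times, func = "cell_derivs",
                         parms = .parms_vec(params), dllname = "rejuvasim",
                         initfunc = "cell_initmod", rootfunc = "cell_root",
                         nroot = 3L, rtol = rtol, atol = atol,
                         maxsteps = 100000L)
  iroot <- attr(out, "iroot")
  n <- nrow(out)
  root <- 0L
  if (!is.null(iroot) && any(iroot > 0)) {
    fired <- which(iroot > 0)
    # death dominates ties, then division, then the health crossing
    root <- if (2L %in% fired) 2L else if (1L %in% fired) 1L else 3L
  }
  list(t = unname(out[n, 1]), y = unname(out[n, 2:3]), root = root,
       traj = if (is.null(dense_dt)) NULL else unclass(out)[, 1:3, drop = FALSE])
}

# tiny fixed RK4 step used to move off a just-located non-terminal root before
# restarting the root-finding integrator
.nudge <- function(y, t, params, dt = 1e-8) {
  f <- function(yy) {
    rhs <- ode_rhs(list(P = yy[1], D = yy[2]), params)
    c(rhs[[1]], rhs[[2]])
  }
  k1 <- f(y); k2 <- f(y + dt / 2 * k1); k3 <- f(y + dt / 2 * k2)
  k4 <- f(y + dt * k3)
  list(t = t + dt, y = y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
}

#' Integrate a cell to its next division, death or the horizon
#'
#' Advances the single-cell dynamics from `state` until the earliest upward
#' crossing of `P` through `P_div` (a division), of `D` through `D_death`
#' (death), or until `t_max` (horizon). Both division and death are treated as
#' instantaneous events; if both roots coincide within the root tolerance,
#' death wins. Root locations are refined by the integrator to ~1e-9 in time.
#'
#' @param state A `cell_state`.
#' @param params A `cell_params`.
#' @param t_max Horizon time, > `state$t`.
#' @param dense_dt Optional time step for storing the dense trajectory.
#' @return A list with `kind` (`"division"`, `"death"` or `"horizon"`), `t`
#'   (event time), `state` (a `cell_state` at the event), `t_health` (first
#'   upward crossing of `D` through `D_health` during this leg, or `NA`), and
#'   `traj` (dense trajectory matrix if requested, else `NULL`).
#' @export
integrate_to_event <- function(state, params, t_max, dense_dt = NULL) {
  if (t_max <= state$t) stop("t_max must exceed state$t")
  # boundary starts: events that are already true fire immediately
  if (state$D >= params$D_death) {
    return(list(kind = "death", t = state$t, state = state,
                t_health = if (state$D >= params$D_health) state$t else NA_real_,
                traj = NULL))
  }
  if (state$P >= params$P_div) {
    return(list(kind = "division", t = state$t, state = state,
                t_health = if (state$D >= params$D_health) state$t else NA_real_,
                traj = NULL))
  }
  t_health <- if (state$D >= params$D_health) state$t else NA_real_
  y <- c(P = state$P, D = state$D)
  t <- state$t
  traj <- NULL
  repeat {
    leg <- tryCatch(
      .integrate_leg(y, t, t_max, params, dense_dt = dense_dt),
      error = function(e) stop("integrator failure at t = ", format(t),
                               ", P = ", format(y[1]), ", D = ", format(y[2]),
                               ": ", conditionMessage(e)))
    if (!is.null(leg$traj)) traj <- rbind(traj, leg$traj)
    t <- leg$t
    y <- leg$y
    if (leg$root == 2L) {
      kind <- "death"
    } else if (leg$root == 1L) {
      kind <- "division"
    } else if (leg$root == 3L) {
      # health crossing: record the first upward one, then continue
      if (is.na(t_health) && y[2] >= params$D_health - 1e-9) t_health <- t
      if (t >= t_max) { kind <- "horizon"; break }
      stepped <- .nudge(y, t, params)
      y <- stepped$y
      t <- stepped$t
      next
    } else {
      kind <- "horizon"
    }
    break
  }
  list(kind = kind, t = t,
       state = cell_state(t = t, P = max(y[[1]], 0), D = min(max(y[[2]], 0), 1)),
       t_health = t_health, traj = traj)
}

#' Partition a dividing cell between mother and daughter
#'
#' At division the functional pool splits by the size proportion: the mother
#' keeps `s*P`, the daughter receives `(1 - s)*P`. Damage splits by size too,
#' but retention pulls the fraction `re` of the daughter-bound damage back
#' into the mother: mother damage `(s + re*(1 - s))*D`, daughter damage
#' `(1 - re)*(1 - s)*D`. Both pools are conserved exactly (the daughter's
#' share is computed as the complement of the mother's).
#'
#' @param state A `cell_state` at the division event (`P >= P_div`).
#' @param params A `cell_params`.
#' @return List with `mother` and `daughter`, both `cell_state`s at the same
#'   time as `state`.
#' @examples
#' p <- wildtype_params("decline")
#' divide(cell_state(0, P = 0.5, D = 0.2), p)
#' @export
divide <- function(state, params) {
  if (state$P < params$P_div - 1e-9)
    stop("divide() requires P >= P_div (division must have been triggered)")
  mP <- params$s * state$P
  mD <- (params$s + params$re * (1 - params$s)) * state$D
  list(mother = cell_state(t = state$t, P = mP, D = mD),
       daughter = cell_state(t = state$t, P = state$P - mP, D = state$D - mD))
}

#' Simulate one cell from birth to death (or a cap)
#'
#' Alternates [integrate_to_event()] and [divide()]: at each division the
#' mother keeps her share and continues, and the daughter's birth state is
#' recorded; the life ends at death (damage reaches `D_death`) or is censored
#' at the division or lifetime cap. Immortal parameterisations (e.g.
#' `k1 = 0`) surface as censored records, never as infinite loops.
#'
#' @param birth A `cell_state` at birth.
#' @param params A `cell_params`.
#' @param max_divisions Cap on the number of divisions (default 1000).
#' @param max_lifetime Cap on the lifetime (default 1e4).
#' @param dense_dt Optional dense-output time step; when given, the full
#'   trajectory is stored in the result (used for trajectory-level checks).
#' @return A list (a cell-record fragment) with fields `birth_state`, `td`
#'   (death time, `NA` if censored), `censored`, `rls`, `division_times`,
#'   `d_at_divisions` (pre-division damage), `sizes_at_divisions`
#'   (pre-division size `S`), `daughters` (list of `cell_state` at birth),
#'   `t_health` (first time `D` reaches `D_health`, `NA` if never),
#'   `state_at_end` and `size_at_end`, and `traj` if requested.
#' @export
simulate_cell <- function(birth, params, max_divisions = 1000L,
                          max_lifetime = 1e4, dense_dt = NULL) {
  stopifnot(max_divisions >= 0, max_lifetime > 0)
  t_end <- birth$t + max_lifetime
  state <- birth
  division_times <- numeric(0)
  d_at_divisions <- numeric(0)
  sizes_at_divisions <- numeric(0)
  daughters <- list()
  t_health <- NA_real_
  traj <- NULL
  censored <- FALSE
  td <- NA_real_
  repeat {
    ev <- integrate_to_event(state, params, t_max = t_end, dense_dt = dense_dt)
    if (!is.null(ev$traj)) traj <- rbind(traj, ev$traj)
    if (is.na(t_health) && !is.na(ev$t_health)) t_health <- ev$t_health
    if (ev$kind == "death") {
      td <- ev$t
      state <- ev$state
      break
    }
    if (ev$kind == "horizon") {
      censored <- TRUE
      state <- ev$state
      break
    }
    # division
    division_times <- c(division_times, ev$t)
    d_at_divisions <- c(d_at_divisions, ev$state$D)
    sizes_at_divisions <- c(sizes_at_divisions,
                            ev$state$P + params$Q * ev$state$D)
    parts <- divide(ev$state, params)
    daughters[[length(daughters) + 1L]] <- parts$daughter
    state <- parts$mother
    if (length(division_times) >= max_divisions) {
      censored <- TRUE
      break
    }
  }
  list(birth_state = birth, td = td, censored = censored,
       rls = length(division_times), division_times = division_times,
       d_at_divisions = d_at_divisions,
       sizes_at_divisions = sizes_at_divisions, daughters = daughters,
       t_health = t_health, state_at_end = state,
       size_at_end = state$P + params$Q * state$D, traj = traj)
}
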