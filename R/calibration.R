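#' Replicative lifespan of a single deterministic founder
#'
#' Simulates one cell with fixed parameters (no mixed effects) from average
#' initial conditions and damage `D0` (damage-free by default) and counts its
#' divisions until death.
#'
#' @param params A `cell_params`.
#' @param D0 Damage at birth.
#' @param max_divisions,max_lifetime Caps passed to [simulate_cell()].
#' @return Integer division count, or `NA_integer_` if the cell is censored at
#'   a cap (e.g. immortal parameterisations such as `k1 = 0`).
#' @export
simulate_rls <- function(params, D0 = 0, max_divisions = 1000L,
                         max_lifetime = 1e4) {
  frag <- simulate_cell(founder_state(params, D0 = D0), params,
                        max_divisions = max_divisions,
                        max_lifetime = max_lifetime)
  if (frag$censored) NA_integer_ else as.integer(frag$rls)
}

# censored lifespans compare as infinite when bracketing the target
.rls_val <- function(x) if (is.na(x)) Inf else as.numeric(x)

# locate, by bisection to `tol`, the boundary in [lo, hi] between
# pred(f(lo)) == TRUE and pred(f(hi)) == FALSE; f is monotone in the sense
# that pred flips exactly once. Returns c(boundary, iterations).
.bisect_edge <- function(f, lo, hi, pred, tol = 1e-6, max_iter = 60L) {
  it <- 0L
  while (hi - lo > tol && it < max_iter) {
    mid <- (lo + hi) / 2
    if (pred(f(mid))) lo <- mid else hi <- mid
    it <- it + 1L
  }
  c((lo + hi) / 2, it)
}

#' Calibrate the retention factor against a target lifespan
#'
#' The replicative lifespan is a non-increasing integer step function of the
#' retention factor (more retention loads the mother with more damage), so the
#' set of `re` attaining the target is an interval (plateau). Both plateau
#' edges are located by bisection and the midpoint is returned as the
#' representative calibrated value. The monotonicity precondition
#' (`rls(re = 0) >= rls(re = 1)`) is checked, not assumed.
#'
#' @param k1,k2 Damage formation and repair rates of the grid point.
#' @param R Repair capacity (`1/pi` or `Inf`).
#' @param target_rls Target replicative lifespan (default 24, the wildtype
#'   yeast average).
#' @param base Base parameters (growth factor, resilience, thresholds); a
#'   `cell_params` or the default shipped base.
#' @param tol Bisection tolerance in `re` (default 1e-6).
#' @param rls_fun Optional function `re -> rls` replacing the simulator
#'   (used for testing the plateau search in isolation).
#' @return List with `feasible` (logical), `re_star` (calibrated retention or
#'   `NA`), `achieved_rls`, `iterations` and the plateau edges `re_lo`,
#'   `re_hi`.
#' @export
calibrate_re <- function(k1, k2, R, target_rls = 24L, base = NULL,
                         tol = 1e-6, rls_fun = NULL) {
  if (is.null(rls_fun)) {
    b <- if (is.null(base)) wildtype_base() else unclass(base)
    rls_fun <- function(re) {
      simulate_rls(cell_params(g = b$g, k1 = k1, k2 = k2, Q = b$Q, R = R,
                               re = re, s = b$s, P_div = b$P_div,
                               D_death = b$D_death, D_health = b$D_health))
    }
  }
  f <- function(re) .rls_val(rls_fun(re))
  infeasible <- list(feasible = FALSE, re_star = NA_real_,
                     achieved_rls = NA_integer_, iterations = 0L,
                     re_lo = NA_real_, re_hi = NA_real_)
  f0 <- f(0)
  f1 <- f(1)
  if (f0 < f1) warning("rls is not non-increasing in re at this grid point ",
                       "(anomaly: rls(0) = ", f0, " < rls(1) = ", f1, ")")
  if (f0 < target_rls || f1 > target_rls) return(infeasible)
  iters <- 0L
  # upper plateau edge: boundary between rls >= target and rls < target
  if (f1 >= target_rls) {
    re_hi <- 1
  } else {
    e <- .bisect_edge(f, 0, 1, function(v) v >= target_rls, tol = tol)
    re_hi <- e[1]; iters <- iters + e[2]
  }
  # lower plateau edge: boundary between rls > target and rls <= target
  if (f0 <= target_rls) {
    re_lo <- 0
  } else {
    e <- .bisect_edge(f, 0, 1, function(v) v > target_rls, tol = tol)
    re_lo <- e[1]; iters <- iters + e[2]
  }
  re_star <- (re_lo + re_hi) / 2
  achieved <- rls_fun(re_star)
  if (is.na(achieved) || achieved != target_rls) return(infeasible)
  list(feasible = TRUE, re_star = re_star, achieved_rls = as.integer(achieved),
       iterations = as.integer(iters), re_lo = re_lo, re_hi = re_hi)
}

#' Calibrate the repair rate against a target lifespan
#'
#' Alternate calibration mode holding `(k1, re)` fixed and adapting `k2`: the
#' lifespan is non-decreasing in the repair rate, so the plateau attaining the
#' target is again found by bisection on both edges.
#'
#' @inheritParams calibrate_re
#' @param re Retention factor held fixed.
#' @param k2_range Search interval for the repair rate.
#' @param rls_fun Optional function `k2 -> rls` replacing the simulator.
#' @return As [calibrate_re()], with `k2_star` in place of `re_star` and edges
#'   `k2_lo`, `k2_hi`.
#' @export
calibrate_k2 <- function(k1, re, R, target_rls = 24L, base = NULL,
                         k2_range = c(0, 1), tol = 1e-6, rls_fun = NULL) {
  if (is.null(rls_fun)) {
    b <- if (is.null(base)) wildtype_base() else unclass(base)
    rls_fun <- function(k2) {
      simulate_rls(cell_params(g = b$g, k1 = k1, k2 = k2, Q = b$Q, R = R,
                               re = re, s = b$s, P_div = b$P_div,
                               D_death = b$D_death, D_health = b$D_health))
    }
  }
  f <- function(k2) .rls_val(rls_fun(k2))
  infeasible <- list(feasible = FALSE, k2_star = NA_real_,
                     achieved_rls = NA_integer_, iterations = 0L,
                     k2_lo = NA_real_, k2_hi = NA_real_)
  lo <- k2_range[1]; hi <- k2_range[2]
  flo <- f(lo)
  fhi <- f(hi)
  if (flo > target_rls || fhi < target_rls) return(infeasible)
  iters <- 0L
  # lower plateau edge: boundary between rls < target and rls >= target
  if (flo >= target_rls) {
    k2_lo <- lo
  } else {
    e <- .bisect_edge(f, lo, hi, function(v) v < target_rls, tol = tol)
    k2_lo <- e[1]; iters <- iters + e[2]
  }
  # upper plateau edge: boundary between rls <= target and rls > target
  if (fhi <= target_rls) {
    k2_hi <- hi
  } else {
    e <- .bisect_edge(f, lo, hi, function(v) v <= target_rls, tol = tol)
    k2_hi <- e[1]; iters <- iters + e[2]
  }
  k2_star <- (k2_lo + k2_hi) / 2
  achieved <- rls_fun(k2_star)
  if (is.na(achieved) || achieved != target_rls) return(infeasible)
  list(feasible = TRUE, k2_star = k2_star, achieved_rls = as.integer(achieved),
       iterations = as.integer(iters), k2_lo = k2_lo, k2_hi = k2_hi)
}

#' Build the wildtype parameter grid
#'
#' For every `(k1, k2)` combination on a regular grid (spacing 0.005 by
#' default) and a given repair-capacity regime, calibrates the retention
#' factor so that an initially damage-free founder achieves the target
#' replicative lifespan; grid points where no retention factor attains the
#' target are marked infeasible.
#'
#' @param k1_range,k2_range Two-element ranges (inclusive).
#' @param spacing Grid spacing for both rates (default 0.005).
#' @param regime `"decline"` (`R = 1/pi`) or `"unlimited"` (`R = Inf`).
#' @param target_rls Target lifespan (default 24).
#' @param base Base parameters, as in [calibrate_re()].
#' @return Data.frame with columns `k1`, `k2`, `R_regime`, `re_star`,
#'   `achieved_rls`, `feasible`.
#' @export
build_wildtype_grid <- function(k1_range, k2_range, spacing = 0.005,
                                regime = c("decline", "unlimited"),
                                target_rls = 24L, base = NULL) {
  regime <- match.arg(regime)
  R <- if (regime == "decline") 1 / pi else Inf
  k1s <- seq(k1_range[1], k1_range[2], by = spacing)
  k2s <- seq(k2_range[1], k2_range[2], by = spacing)
  grid <- expand.grid(k1 = k1s, k2 = k2s, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(r) {
    cal <- calibrate_re(grid$k1[r], grid$k2[r], R, target_rls = target_rls,
                        base = base)
    data.frame(k1 = grid$k1[r], k2 = grid$k2[r], R_regime = regime,
               re_star = cal$re_star, achieved_rls = cal$achieved_rls,
               feasible = cal$feasible)
  })
  do.call(rbind, res)
}
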