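# Independent fixed-step RK4 oracle for the single-cell dynamics.
#
# Deliberately shares no code with the package's event-detecting integrator:
# the right-hand side is written out inline, events are detected by sign
# change on a fixed dt = 1e-4 grid and refined by bisection on single RK4
# steps. Division applies the partition rule and continues with the mother.

rk4_rhs <- function(P, D, g, k1, k2, Q, R) {
  r <- if (is.finite(R)) k2 * R * sin(D / R) else k2 * D
  S <- P + Q * D
  c(g * P * (1 - S) - k1 * P + r, k1 * P - r)
}

rk4_step <- function(P, D, h, g, k1, k2, Q, R) {
  a <- rk4_rhs(P, D, g, k1, k2, Q, R)
  b <- rk4_rhs(P + h / 2 * a[1], D + h / 2 * a[2], g, k1, k2, Q, R)
  cc <- rk4_rhs(P + h / 2 * b[1], D + h / 2 * b[2], g, k1, k2, Q, R)
  d <- rk4_rhs(P + h * cc[1], D + h * cc[2], g, k1, k2, Q, R)
  c(P + h / 6 * (a[1] + 2 * b[1] + 2 * cc[1] + d[1]),
    D + h / 6 * (a[2] + 2 * b[2] + 2 * cc[2] + d[2]))
}

# refine the event time within one step [t, t + h] by bisection
rk4_refine <- function(P, D, t, h, target_fun, g, k1, k2, Q, R,
                       tol = 1e-10) {
  lo <- 0; hi <- h
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    y <- rk4_step(P, D, mid, g, k1, k2, Q, R)
    if (target_fun(y[1], y[2]) >= 0) hi <- mid else lo <- mid
  }
  list(t = t + (lo + hi) / 2,
       y = rk4_step(P, D, (lo + hi) / 2, g, k1, k2, Q, R))
}

rk4_simulate_cell <- function(birth, params, dt = 1e-4,
                              max_divisions = 100L, max_lifetime = 400) {
  g <- params$g; k1 <- params$k1; k2 <- params$k2; Q <- params$Q
  R <- params$R; Pdiv <- params$P_div; Dd <- params$D_death
  s <- params$s; re <- params$re
  P <- birth$P; D <- birth$D; t <- birth$t
  t_end <- birth$t + max_lifetime
  division_times <- numeric(0)
  td <- NA_real_
  censored <- FALSE
  repeat {
    y <- rk4_step(P, D, dt, g, k1, k2, Q, R)
    tn <- t + dt
    div_hit <- y[1] >= Pdiv
    death_hit <- y[2] >= Dd
    if (death_hit || div_hit) {
      # locate both candidate crossings; the earlier one wins, death on ties
      cand_t <- c(Inf, Inf)
      if (div_hit) {
        rf <- rk4_refine(P, D, t, dt, function(p, d) p - Pdiv,
                         g, k1, k2, Q, R)
        cand_t[1] <- rf$t; div_ref <- rf
      }
      if (death_hit) {
        rf <- rk4_refine(P, D, t, dt, function(p, d) d - Dd,
                         g, k1, k2, Q, R)
        cand_t[2] <- rf$t; death_ref <- rf
      }
      if (cand_t[2] <= cand_t[1]) {
        td <- death_ref$t
        break
      }
      # division: partition and continue with the mother
      t <- div_ref$t
      P <- s * div_ref$y[1]
      D <- (s + re * (1 - s)) * div_ref$y[2]
      division_times <- c(division_times, t)
      if (length(division_times) >= max_divisions) { censored <- TRUE; break }
      next
    }
    P <- y[1]; D <- y[2]; t <- tn
    if (t >= t_end) { censored <- TRUE; break }
  }
  list(rls = length(division_times), division_times = division_times,
       td = td, censored = censored)
}
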