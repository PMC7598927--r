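test_that("repair flux matches the analytic form, its limits and its domain", {
  # zero damage: no repair regardless of rate or capacity
  expect_identical(repair_rate(0, 0.2, 1), 0)
  expect_identical(repair_rate(0, 0.138, Inf), 0)
  # minimal capacity: effective repair collapses to zero at full damage load
  expect_lt(abs(repair_rate(1, 0.138, 1 / pi)), 1e-12)
  # peak of the declining profile (independent high-precision evaluation)
  expect_equal(repair_rate(0.5, 0.138, 1 / pi), 0.043926764293363113,
               tolerance = 1e-14)
  # small-angle / unlimited-capacity limit is linear repair
  expect_equal(repair_rate(0.3, 0.092, 1e6), 0.092 * 0.3, tolerance = 1e-10)
  expect_identical(repair_rate(0.3, 0.092, Inf), 0.092 * 0.3)
  # domain errors
  expect_error(repair_rate(-0.1, 0.1, 1), "\\[0, 1\\]")
  expect_error(repair_rate(1.2, 0.1, 1), "\\[0, 1\\]")
  expect_error(repair_rate(0.5, 0.1, 0.2), "1/pi")
})

test_that("repair flux converges to linear repair within the analytic bound", {
  Ds <- seq(0, 1, by = 0.05)
  k2 <- 0.138
  # the bound is analytically tight as D -> 0, so allow a few ulps of k2 for
  # floating-point rounding of the evaluation itself
  fp <- 64 * .Machine$double.eps * k2
  for (R in c(1e3, 1e4, 1e6)) {
    err <- abs(repair_rate(Ds, k2, R) - k2 * Ds)
    expect_true(all(err <= k2 * Ds^3 / (6 * R^2) + fp))
  }
})

test_that("repair flux is non-decreasing in the capacity", {
  Ds <- c(0.05, 0.3, 0.5, 0.9, 1)
  Rs <- c(1 / pi, 0.4, 0.6, 1, 3, 10, 1e3, Inf)
  for (D in Ds) {
    v <- vapply(Rs, function(R) repair_rate(D, 0.1, R), numeric(1))
    expect_true(all(diff(v) >= -1e-15))
  }
})

test_that("ode right-hand side moves mass between pools and fixes the origin", {
  p <- cell_params(g = 1, k1 = 0.4, k2 = 0.138, Q = 1, R = 1 / pi,
                   re = 0, s = 0.64, P_div = 0.5)
  # frozen values from an independent symbolic evaluation of the adopted RHS
  d <- ode_rhs(list(P = 0.3, D = 0.1), p)
  expect_equal(unname(d[1]), 0.07357411667455183, tolerance = 1e-14)
  expect_equal(unname(d[2]), 0.10642588332544817, tolerance = 1e-14)
  # formation and repair only exchange mass: total flux is the growth flux
  for (st in list(list(P = 0.1, D = 0.02), list(P = 0.45, D = 0.7),
                  list(P = 0.3, D = 0.1))) {
    dd <- ode_rhs(st, p)
    expect_equal(sum(dd), p$g * st$P * (1 - (st$P + p$Q * st$D)),
                 tolerance = 1e-15)
  }
  # extinction fixed point
  expect_identical(unname(ode_rhs(list(P = 0, D = 0), p)), c(0, 0))
  # no damage source: damage stays flat, growth positive below unit size
  p0 <- cell_params(g = 1, k1 = 0, k2 = 0.1, Q = 1, R = Inf)
  d0 <- ode_rhs(list(P = 0.3, D = 0), p0)
  expect_identical(unname(d0[2]), 0)
  expect_gt(d0[1], 0)
})

test_that("division partitions both pools exactly by size and retention", {
  p <- wildtype_params("decline")  # s = 0.64, re = 0.2957
  out <- divide(cell_state(0, P = 0.5, D = 0.2), p)
  expect_equal(out$mother$P, 0.32, tolerance = 1e-15)
  expect_equal(out$mother$D, 0.1492904, tolerance = 1e-15)
  expect_equal(out$daughter$P, 0.18, tolerance = 1e-15)
  expect_equal(out$daughter$D, 0.0507096, tolerance = 1e-12)
  # conservation is exact (complement construction), on arbitrary states
  set.seed(42)
  for (i in 1:50) {
    P <- runif(1, 0.5, 2)
    D <- runif(1)
    o <- divide(cell_state(0, P = P, D = D), p)
    expect_identical(o$mother$P + o$daughter$P, P)
    expect_identical(o$mother$D + o$daughter$D, D)
  }
  # no retention: damage splits by pure size proportion (64 % to the mother)
  p0 <- wildtype_params("decline", re = 0)
  o0 <- divide(cell_state(0, P = 0.5, D = 0.3), p0)
  expect_equal(o0$mother$D / 0.3, 0.64, tolerance = 1e-15)
  # full retention: the daughter is born damage-free
  p1 <- wildtype_params("decline", re = 1)
  o1 <- divide(cell_state(0, P = 0.5, D = 0.3), p1)
  expect_identical(o1$daughter$D, 0)
  # division requires the trigger
  expect_error(divide(cell_state(0, P = 0.1, D = 0), p), "P_div")
})

test_that("integrate_to_event handles boundary starts and monotone growth", {
  p <- wildtype_params("decline")
  # already at the death threshold: death fires at the start time
  ev <- integrate_to_event(cell_state(3, P = 0.2, D = 1), p, t_max = 10)
  expect_identical(ev$kind, "death")
  expect_identical(ev$t, 3)
  # no damage formation: growth is monotone, division is certain
  p0 <- wildtype_params("decline", k1 = 0)
  ev0 <- integrate_to_event(founder_state(p0), p0, t_max = 50)
  expect_identical(ev0$kind, "division")
  expect_equal(ev0$state$P, p0$P_div, tolerance = 1e-8)
  expect_lt(abs(ev0$state$D), 1e-12)
  # horizon: nothing happens in a too-short window
  evh <- integrate_to_event(founder_state(p), p, t_max = 0.5)
  expect_identical(evh$kind, "horizon")
  expect_error(integrate_to_event(founder_state(p), p, t_max = -1), "t_max")
})

test_that("event detection matches the fixed-step RK4 oracle on wildtype founders", {
  for (reg in c("decline", "unlimited")) {
    p <- wildtype_params(reg)
    frag <- simulate_cell(founder_state(p), p)
    oracle <- rk4_simulate_cell(founder_state(p), p, dt = 1e-4,
                                max_divisions = 100, max_lifetime = 400)
    expect_false(frag$censored)
    expect_identical(frag$rls, oracle$rls)
    expect_lt(max(abs(frag$division_times - oracle$division_times)), 1e-5)
    expect_lt(abs(frag$td - oracle$td), 1e-5)
  }
})

test_that("sterile and immortal parameterisations are handled", {
  # damage overwhelms before the first division: zero lifespan, one death
  ps <- wildtype_params("decline", k1 = 4)
  frag <- simulate_cell(founder_state(ps), ps)
  expect_identical(frag$rls, 0L)
  expect_false(frag$censored)
  expect_true(is.finite(frag$td))
  # no ageing source: censored at the division cap, never an infinite loop
  pi0 <- wildtype_params("decline", k1 = 0)
  fr0 <- simulate_cell(founder_state(pi0), pi0, max_divisions = 15L)
  expect_true(fr0$censored)
  expect_identical(fr0$rls, 15L)
  expect_true(is.na(fr0$td))
})

test_that("simulated trajectories stay inside the admissible domain", {
  for (k1 in c(0.4, 0.8)) {
    p <- wildtype_params("decline", k1 = k1)
    frag <- simulate_cell(founder_state(p), p, dense_dt = 0.01)
    expect_true(all(frag$traj[, 3] <= p$D_death + 1e-6))
    expect_true(all(frag$traj[, 2] >= -1e-12))
    # death time strictly after the last division
    if (frag$rls > 0) expect_gt(frag$td, max(frag$division_times))
  }
})

test_that("lifespan is non-increasing in the retention factor", {
  res <- seq(0, 1, by = 0.1)
  rls <- vapply(res, function(re) {
    p <- wildtype_params("decline", re = re)
    v <- simulate_rls(p, max_divisions = 60L, max_lifetime = 400)
    if (is.na(v)) 1e9 else as.numeric(v)  # censored = at least the cap
  }, numeric(1))
  expect_true(all(diff(rls) <= 0))
})
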