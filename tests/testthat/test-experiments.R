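# Structural checks of the experiment drivers on deliberately small designs;
# the directional claims on the shipped wildtype scenario live in
# test-acceptance.R.

tiny_design <- function(name, ...) {
  experiment_design(name, n_founders = 1L, max_generation = 1L,
                    max_cells = 500L, sigma = 0.005, seeds = 1L, ...)
}

test_that("retention sweep emits one summary row per feasible arm", {
  des <- tiny_design("sweep", re_values = c(0, 0.2957), regimes = "decline")
  res <- run_retention_sweep(des)
  expect_identical(nrow(res), 2L)
  expect_setequal(res$re, c(0, 0.2957))
  expect_true(all(res$population_size > 1))
  expect_true(all(is.finite(res$mean_damage_at_birth)))
  # infeasible pairings are skipped with a message, not an error
  des_bad <- tiny_design("sweep", re_values = 1, regimes = "unlimited",
                         k1 = 0.8)
  expect_message(res_bad <- run_retention_sweep(des_bad), "infeasible")
  expect_null(res_bad)
})

test_that("division-age table reproduces the partition rule at every age", {
  des <- tiny_design("divage", re_values = 0.2957, regimes = "decline")
  res <- run_division_age_analysis(des)
  # mother keeps s + re(1-s) of the pre-division damage at every age
  share <- 0.64 + 0.2957 * 0.36
  expect_equal(res$D_mother, share * res$D_pre, tolerance = 1e-14)
  expect_equal(res$D_daughter, (1 - share) * res$D_pre, tolerance = 1e-12)
  expect_equal(res$P_daughter + res$P_mother, res$P_pre, tolerance = 1e-14)
  # age-1 daughters: damage equals (1-re)(1-s) D(t1) exactly
  a1 <- res[res$mother_age == 1, ]
  expect_equal(a1$D_daughter, (1 - 0.2957) * 0.36 * a1$D_pre,
               tolerance = 1e-12)
  # ages run 1..rls per cell
  expect_true(all(tapply(res$mother_age, res$cell_id,
                         function(v) identical(as.integer(v),
                                               seq_along(v)))))
})

test_that("growth-rate driver counts match filtering the exported table", {
  des <- experiment_design("growth", n_founders = 1L, sigma = 0.005,
                           seeds = 1:3, re_values = 0.2957,
                           regimes = "decline", snapshot_time = 6)
  res <- run_growth_rate_experiment(des)
  expect_identical(nrow(res), 3L)
  # recompute one count through the exported lineage table
  p <- wildtype_params("decline",
                       k2 = calibrate_k2(0.4, 0.2957, 1 / pi)$k2_star)
  tab <- run_population(p, n_founders = 1L, sigma = 0.005, seed = 2L,
                        max_generation = 1000L, max_cells = 500L, t_max = 6)
  base <- file.path(tempdir(), "growth")
  export_lineage(tab, base)
  csv <- read.csv(paste0(base, ".csv"))
  expect_identical(res$count_at_snapshot[res$seed == 2L],
                   sum(as.numeric(csv$t0) <= 6))
  # a snapshot before the first division sees exactly the founder
  des0 <- experiment_design("growth0", n_founders = 1L, sigma = 0,
                            seeds = 1L, re_values = 0.2957,
                            regimes = "decline", snapshot_time = 0.5)
  res0 <- run_growth_rate_experiment(des0)
  expect_identical(res0$count_at_snapshot, 1L)
})

test_that("stress scales every sampled k1 by exactly the multiplier", {
  des <- tiny_design("stress", re_values = 0.2957, regimes = "decline",
                     stress_multiplier = 1.01)
  res <- run_stress_experiment(des)
  pops <- res$populations
  expect_identical(nrow(pops), 2L)
  # common random numbers: identical positions draw identical effects, so the
  # sampled k1 of matched cells differ by exactly the multiplier
  p <- wildtype_params("decline",
                       k2 = calibrate_k2(0.4, 0.2957, 1 / pi)$k2_star)
  unstressed <- run_population(p, n_founders = 1L, sigma = 0.005, seed = 1L,
                               max_generation = 1L, max_cells = 500L)
  stressed <- run_population(p, n_founders = 1L, sigma = 0.005, seed = 1L,
                             max_generation = 1L, max_cells = 500L,
                             stress_multiplier = 1.01)
  key <- function(t) paste(t$cells$founder, t$cells$position)
  m <- match(key(stressed), key(unstressed))
  ok <- !is.na(m)
  expect_gt(sum(ok), 5)
  expect_equal(stressed$cells$k1[ok], 1.01 * unstressed$cells$k1[m[ok]],
               tolerance = 1e-15)
  # a multiplier of 1 reproduces the unstressed run exactly
  same <- run_population(p, n_founders = 1L, sigma = 0.005, seed = 1L,
                         max_generation = 1L, max_cells = 500L,
                         stress_multiplier = 1)
  expect_identical(same, unstressed)
})

test_that("mixed-effects comparison: degenerate sigma collapses variability", {
  des <- tiny_design("mix", re_values = 0.2957, regimes = "decline")
  res <- run_mixed_effects_comparison(des)
  expect_identical(nrow(res), 2L)
  r0 <- res[res$sigma == 0, ]
  rv <- res[res$sigma > 0, ]
  # sigma = 0: every cell shares the fixed effects
  p <- wildtype_params("decline",
                       k2 = calibrate_k2(0.4, 0.2957, 1 / pi)$k2_star)
  tab0 <- run_population(p, n_founders = 1L, sigma = 0, seed = 1L,
                         max_generation = 1L, max_cells = 500L)
  expect_identical(unique(tab0$cells$k1), p$k1)
  # nondegenerate noise produces positive lifespan dispersion
  expect_gt(rv$sd_rls, 0)
})

test_that("correlation tables join back to cell ids losslessly", {
  tab <- small_wt_table(max_generation = 1L, n_founders = 2L)
  res <- run_correlation_analysis(tab)
  expect_setequal(unique(res$pairing),
                  c("health_span_vs_rls",
                    "generation_time_vs_growth_per_cycle",
                    "lineage_index_vs_rls",
                    "size_at_birth_vs_cumulative_growth"))
  m <- cell_metrics(tab)
  # the rejuvenated flag equals an independent recomputation
  sub <- res[res$pairing == "health_span_vs_rls", ]
  rej <- m$rejuvenation_index[match(sub$cell_id, m$cell_id)]
  expect_identical(sub$rejuvenated, !is.na(rej) & rej > 0)
  # pairs carry the metric values keyed by cell id
  expect_equal(sub$x, m$health_span[match(sub$cell_id, m$cell_id)])
  expect_equal(sub$y, as.numeric(m$rls[match(sub$cell_id, m$cell_id)]))
})

test_that("every driver is a pure function of its design and seeds", {
  des <- tiny_design("rerun", re_values = c(0, 0.2957), regimes = "decline")
  expect_identical(run_retention_sweep(des), run_retention_sweep(des))
  expect_identical(run_division_age_analysis(des),
                   run_division_age_analysis(des))
  desg <- experiment_design("g", n_founders = 1L, sigma = 0.005, seeds = 1:2,
                            re_values = 0.2957, regimes = "decline",
                            snapshot_time = 5)
  expect_identical(run_growth_rate_experiment(desg),
                   run_growth_rate_experiment(desg))
  dess <- tiny_design("s", re_values = 0.2957, regimes = "decline")
  expect_identical(run_stress_experiment(dess), run_stress_experiment(dess))
  expect_identical(run_mixed_effects_comparison(dess),
                   run_mixed_effects_comparison(dess))
  tab <- small_wt_table(max_generation = 1L)
  expect_identical(run_correlation_analysis(tab),
                   run_correlation_analysis(tab))
})
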