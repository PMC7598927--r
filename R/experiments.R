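#' Experiment design
#'
#' Bundles everything a scripted experiment driver needs: founder count and
#' initial damage, stopping caps, mixed-effects level, parameter sweeps,
#' explicit seeds (no wall-clock seeding) and the wildtype anchor `k1`.
#' Defaults reproduce the shipped scaled-down wildtype scenarios; the founder
#' counts follow the published designs (5 founders for the retention sweep, 10
#' for division-age and stress analyses, 20 single-founder populations for the
#' growth-rate experiment).
#'
#' @param name Experiment name.
#' @param n_founders Founders per population.
#' @param founder_D0 Damage at birth of the founders.
#' @param max_generation Generation cap.
#' @param max_cells Cell cap per population.
#' @param t_max Absolute time horizon (`Inf` = generation-cap mode).
#' @param sigma Mixed-effects standard deviation.
#' @param seeds Integer vector of RNG seeds (one population per seed where the
#'   design calls for replicates).
#' @param re_values Retention factors to sweep.
#' @param regimes Repair-capacity regimes to include.
#' @param k1 Damage formation fixed effect (wildtype anchor 0.4).
#' @param stress_multiplier Stress factor applied to `k1`.
#' @param h_c Healthy-cell cutoff.
#' @param snapshot_time Growth-proxy snapshot time.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(name, n_founders = 5L, founder_D0 = 0,
                              max_generation = 2L, max_cells = 4000L,
                              t_max = Inf, sigma = 0.005, seeds = 1L,
                              re_values = c(0, 0.2957),
                              regimes = c("decline", "unlimited"),
                              k1 = 0.4, stress_multiplier = 1.01,
                              h_c = 0.5, snapshot_time = 8) {
  structure(list(name = name, n_founders = as.integer(n_founders),
                 founder_D0 = founder_D0,
                 max_generation = as.integer(max_generation),
                 max_cells = as.integer(max_cells), t_max = t_max,
                 sigma = sigma, seeds = as.integer(seeds),
                 re_values = re_values, regimes = regimes, k1 = k1,
                 stress_multiplier = stress_multiplier, h_c = h_c,
                 snapshot_time = snapshot_time),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(
    "<experiment_design> '%s': %d founder(s), gen cap %d, sigma %g, %d seed(s)\n",
    x$name, x$n_founders, x$max_generation, x$sigma, length(x$seeds)))
  invisible(x)
}

# matched-lifespan parameters for a (re, regime) arm: k1 fixed, k2 adapted by
# calibration so every arm starts from founders with the same target lifespan.
# Calibration is deterministic, so results are cached for the session.
.calibration_cache <- new.env(parent = emptyenv())

.matched_params <- function(k1, re, regime, target_rls = 24L) {
  key <- paste(format(k1, digits = 15), format(re, digits = 15), regime,
               target_rls, sep = "|")
  hit <- .calibration_cache[[key]]
  if (!is.null(hit)) return(if (isFALSE(hit)) NULL else hit)
  R <- if (regime == "decline") 1 / pi else Inf
  cal <- calibrate_k2(k1, re, R, target_rls = target_rls)
  out <- if (!cal$feasible) FALSE else
    wildtype_params(regime, re = re, k1 = k1, k2 = cal$k2_star)
  assign(key, out, envir = .calibration_cache)
  if (isFALSE(out)) NULL else out
}

.run_arm <- function(design, params, seed, sigma = design$sigma,
                     stress_multiplier = 1) {
  run_population(params, n_founders = design$n_founders, sigma = sigma,
                 seed = seed, max_generation = design$max_generation,
                 max_cells = design$max_cells, t_max = design$t_max,
                 founder_D0 = design$founder_D0,
                 stress_multiplier = stress_multiplier)
}

#' Retention sweep over matched-lifespan wildtype populations
#'
#' For every requested retention factor and repair-capacity regime, adapts the
#' repair rate so that a deterministic damage-free founder keeps the wildtype
#' target lifespan, simulates one population per seed, and summarises
#' population size and the mean and standard deviation of damage at birth,
#' generation time and health span. Infeasible `(re, regime)` pairings are
#' skipped with a message.
#'
#' @param design An [experiment_design()].
#' @return Data.frame, one row per `(re, regime, seed)`.
#' @export
run_retention_sweep <- function(design) {
  out <- list()
  for (regime in design$regimes) {
    for (re in design$re_values) {
      params <- .matched_params(design$k1, re, regime)
      if (is.null(params)) {
        message("skipping infeasible pairing: re = ", re, ", ", regime)
        next
      }
      for (seed in design$seeds) {
        tab <- .run_arm(design, params, seed)
        m <- cell_metrics(tab)
        unc <- !m$censored
        ps <- population_summary(tab, h_c = design$h_c,
                                 snapshot_time = design$snapshot_time)
        out[[length(out) + 1L]] <- data.frame(
          re = re, regime = regime, seed = seed, k2 = params$k2,
          population_size = ps$population_size,
          mean_rls = ps$mean_rls, sd_rls = ps$sd_rls,
          fraction_rejuvenated = ps$fraction_rejuvenated,
          fraction_healthy = ps$fraction_healthy,
          mean_damage_at_birth = mean(m$damage_at_birth),
          sd_damage_at_birth = stats::sd(m$damage_at_birth),
          mean_generation_time = mean(m$mean_generation_time[unc], na.rm = TRUE),
          sd_generation_time = stats::sd(m$mean_generation_time[unc], na.rm = TRUE),
          mean_health_span = mean(m$health_span[unc]),
          sd_health_span = stats::sd(m$health_span[unc]))
      }
    }
  }
  do.call(rbind, out)
}

#' Mother and daughter protein content by replicative age of the mother
#'
#' Long-format table of the protein partition at every recorded division:
#' for a mother of replicative age `n` (her n-th division), the functional and
#' damaged content of mother and daughter immediately after the split, per
#' retention factor and regime arm. Boxplot-ready; also the basis of the
#' daughter-damage-versus-mother-age comparison across arms.
#'
#' @param design An [experiment_design()] (10 founders in the published
#'   layout).
#' @return Data.frame with columns `re`, `regime`, `seed`, `cell_id`,
#'   `mother_age`, `P_pre`, `D_pre`, `P_mother`, `D_mother`, `P_daughter`,
#'   `D_daughter`.
#' @export
run_division_age_analysis <- function(design) {
  out <- list()
  for (regime in design$regimes) {
    for (re in design$re_values) {
      params <- .matched_params(design$k1, re, regime)
      if (is.null(params)) {
        message("skipping infeasible pairing: re = ", re, ", ", regime)
        next
      }
      for (seed in design$seeds) {
        tab <- .run_arm(design, params, seed)
        cells <- tab$cells
        rows <- lapply(seq_len(nrow(cells)), function(r) {
          nd <- length(cells$division_times[[r]])
          if (nd == 0) return(NULL)
          Dpre <- cells$d_at_divisions[[r]]
          Ppre <- rep(params$P_div, nd)
          mshare <- params$s + params$re * (1 - params$s)
          data.frame(re = re, regime = regime, seed = seed,
                     cell_id = cells$cell_id[r], mother_age = seq_len(nd),
                     P_pre = Ppre, D_pre = Dpre,
                     P_mother = params$s * Ppre, D_mother = mshare * Dpre,
                     P_daughter = (1 - params$s) * Ppre,
                     D_daughter = Dpre - mshare * Dpre)
        })
        out[[length(out) + 1L]] <- do.call(rbind, rows)
      }
    }
  }
  do.call(rbind, out)
}

#' Early-growth experiment: cells born by a snapshot time
#'
#' Simulates many single-founder populations in time-horizon mode and counts
#' the cells born by the snapshot time (dimensionless `t = 8` in the published
#' layout), a proxy for the population growth rate in the exponential phase.
#'
#' @param design An [experiment_design()]; one population per seed (20 seeds
#'   in the published layout). `re_values[1]` is used for every arm.
#' @return Data.frame with one row per `(regime, seed)`: the cell count at the
#'   snapshot and the population size simulated.
#' @export
run_growth_rate_experiment <- function(design) {
  out <- list()
  re <- design$re_values[1]
  for (regime in design$regimes) {
    params <- .matched_params(design$k1, re, regime)
    if (is.null(params)) {
      message("skipping infeasible pairing: re = ", re, ", ", regime)
      next
    }
    for (seed in design$seeds) {
      tab <- run_population(params, n_founders = 1L, sigma = design$sigma,
                            seed = seed, max_generation = 1000L,
                            max_cells = design$max_cells,
                            t_max = design$snapshot_time,
                            founder_D0 = design$founder_D0)
      out[[length(out) + 1L]] <- data.frame(
        regime = regime, seed = seed, re = re,
        count_at_snapshot = sum(tab$cells$t0 <= design$snapshot_time),
        population_size = nrow(tab$cells))
    }
  }
  do.call(rbind, out)
}

#' Stress experiment: increased damage formation
#'
#' Runs matched stressed and unstressed populations (stress multiplies the
#' `k1` fixed effect, 1% in the published layout) on common random numbers
#' and returns the rejuvenation index and health span grouped by the
#' grandmother index `j`, plus per-arm population sizes.
#'
#' @param design An [experiment_design()] (10 founders in the published
#'   layout). `re_values[1]` and `regimes[1]` define the arm.
#' @return List with `by_position` (long data.frame: `stress`, `j`, metric
#'   summaries) and `populations` (per-seed sizes for both arms).
#' @export
run_stress_experiment <- function(design) {
  re <- design$re_values[1]
  regime <- design$regimes[1]
  params <- .matched_params(design$k1, re, regime)
  if (is.null(params)) stop("infeasible pairing: re = ", re, ", ", regime)
  bypos <- list()
  pops <- list()
  for (stress in c(FALSE, TRUE)) {
    mult <- if (stress) design$stress_multiplier else 1
    for (seed in design$seeds) {
      tab <- .run_arm(design, params, seed, stress_multiplier = mult)
      m <- cell_metrics(tab)
      g2 <- m[!is.na(m$j) & !m$censored, , drop = FALSE]
      if (nrow(g2) > 0) {
        agg <- do.call(rbind, lapply(split(g2, g2$j), function(gg) {
          data.frame(stress = stress, seed = seed, j = gg$j[1],
                     n = nrow(gg),
                     mean_rejuvenation = mean(gg$rejuvenation_index,
                                              na.rm = TRUE),
                     fraction_rejuvenated =
                       mean(gg$rejuvenation_index > 0, na.rm = TRUE),
                     mean_health_span = mean(gg$health_span, na.rm = TRUE))
        }))
        bypos[[length(bypos) + 1L]] <- agg
      }
      pops[[length(pops) + 1L]] <- data.frame(
        stress = stress, seed = seed, population_size = nrow(tab$cells),
        mean_k1 = mean(tab$cells$k1))
    }
  }
  list(by_position = do.call(rbind, bypos),
       populations = do.call(rbind, pops))
}

#' Mixed-effects comparison: homogeneous versus variable rate parameters
#'
#' Simulates matched populations with `sigma = 0` (all cells share the fixed
#' effects) and with the design's `sigma` (log-normal cell-to-cell
#' variability) on the same seeds, and returns side-by-side population
#' summaries.
#'
#' @param design An [experiment_design()].
#' @return Data.frame with one row per `(sigma, regime, seed)`.
#' @export
run_mixed_effects_comparison <- function(design) {
  re <- design$re_values[1]
  out <- list()
  for (regime in design$regimes) {
    params <- .matched_params(design$k1, re, regime)
    if (is.null(params)) {
      message("skipping infeasible pairing: re = ", re, ", ", regime)
      next
    }
    for (sigma in c(0, design$sigma)) {
      for (seed in design$seeds) {
        tab <- .run_arm(design, params, seed, sigma = sigma)
        ps <- population_summary(tab, h_c = design$h_c,
                                 snapshot_time = design$snapshot_time)
        out[[length(out) + 1L]] <- cbind(
          data.frame(sigma = sigma, regime = regime, re = re, seed = seed),
          ps)
      }
    }
  }
  do.call(rbind, out)
}

#' Paired-metric tables for correlation analysis
#'
#' Emits per-cell metric pairs from a completed lineage table: health span vs
#' replicative lifespan, mean generation time vs mean growth per cycle,
#' lineage index `i` vs lifespan, and size at birth vs cumulative growth, each
#' with a rejuvenated flag, in long format keyed by `cell_id`.
#'
#' @param table A `lineage_table`.
#' @return Data.frame with columns `cell_id`, `pairing`, `x`, `y`,
#'   `rejuvenated`.
#' @export
run_correlation_analysis <- function(table) {
  m <- cell_metrics(table)
  m <- m[!m$censored, , drop = FALSE]
  rej <- !is.na(m$rejuvenation_index) & m$rejuvenation_index > 0
  mk <- function(pairing, x, y) {
    keep <- !is.na(x) & !is.na(y)
    data.frame(cell_id = m$cell_id[keep], pairing = pairing,
               x = x[keep], y = y[keep], rejuvenated = rej[keep])
  }
  rbind(
    mk("health_span_vs_rls", m$health_span, m$rls),
    mk("generation_time_vs_growth_per_cycle",
       m$mean_generation_time, m$mean_growth_per_cycle),
    mk("lineage_index_vs_rls", m$i, m$rls),
    mk("size_at_birth_vs_cumulative_growth",
       m$size_at_birth, m$cumulative_growth))
}
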