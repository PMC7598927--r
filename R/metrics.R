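#' Rejuvenation index
#'
#' Degree of rejuvenation of a non-founder cell: the difference between the
#' cell's and its mother's replicative lifespan, scaled by the population's
#' average replicative lifespan. A rejuvenated cell has a positive index.
#'
#' @param rls_cell Replicative lifespan of the cell.
#' @param rls_mother Replicative lifespan of its mother.
#' @param mean_rls Average replicative lifespan in the population, > 0.
#' @return `(rls_cell - rls_mother) / mean_rls` (vectorised).
#' @examples
#' rejuvenation_index(24, 20, 22)  # 4/22
#' @export
rejuvenation_index <- function(rls_cell, rls_mother, mean_rls) {
  if (any(is.na(rls_mother)))
    stop("rejuvenation index is undefined for founder cells (no mother)")
  if (mean_rls <= 0) stop("mean_rls must be > 0")
  (rls_cell - rls_mother) / mean_rls
}

# health span from the stored first-crossing time.
# rls_c/rls is taken as 1 when rls = 0 (the 0/0 case), leaving h the pure
# time fraction; if damage never reaches the threshold, tc = td and h = 1.
.health_span_scalar <- function(t0, td, tc, division_times) {
  rls <- length(division_times)
  if (is.na(tc)) return(1)
  frac_div <- if (rls == 0) 1 else sum(division_times <= tc + 1e-12) / rls
  ((tc - t0) / (td - t0)) * frac_div
}

#' Health span of a cell
#'
#' Fraction of the cell's lifespan spent below the damage threshold
#' `D_health`, weighted by the fraction of its divisions completed before
#' first crossing the threshold:
#' `h = ((tc - t0) / (td - t0)) * (rls_c / rls)`, where `tc` is the first time
#' damage reaches `D_health` and `rls_c` the number of divisions completed by
#' then. If damage never reaches the threshold, `h = 1`. For `rls = 0` the
#' division factor (0/0) is defined as 1, leaving the pure time fraction.
#'
#' @param table A `lineage_table`.
#' @param cell_id Cell id(s); default all cells.
#' @return Numeric vector of health spans in `[0, 1]`; errors for censored
#'   cells (their death time, hence lifespan, is unknown).
#' @export
health_span <- function(table, cell_id = table$cells$cell_id) {
  cells <- table$cells
  rows <- match(cell_id, cells$cell_id)
  if (any(is.na(rows))) stop("unknown cell id(s)")
  if (any(cells$censored[rows]))
    stop("health span is undefined for censored cells")
  vapply(rows, function(r) {
    .health_span_scalar(cells$t0[r], cells$td[r], cells$t_health[r],
                        cells$division_times[[r]])
  }, numeric(1))
}

#' Health span recomputed from a dense trajectory
#'
#' Independent of the event integrator's stored crossing time: scans a dense
#' trajectory (as stored by `simulate_cell(..., dense_dt = )`) for the first
#' upward crossing of damage through `d_health`, locating it by linear
#' interpolation, and applies the health-span formula. Useful for checking
#' stored values and for evaluating alternative thresholds on the same life.
#'
#' @param traj Matrix with columns `time`, `P`, `D`.
#' @param t0,td Birth and death times.
#' @param division_times Division times of the cell.
#' @param d_health Damage threshold.
#' @return Health span in `[0, 1]`.
#' @export
health_span_from_trajectory <- function(traj, t0, td, division_times,
                                        d_health) {
  D <- traj[, 3]
  tt <- traj[, 1]
  hit <- which(D >= d_health)
  if (length(hit) == 0) return(1)
  i <- hit[1]
  tc <- if (i == 1) tt[1] else {
    # linear interpolation of the crossing within the bracketing interval
    tt[i - 1] + (d_health - D[i - 1]) / (D[i] - D[i - 1]) * (tt[i] - tt[i - 1])
  }
  .health_span_scalar(t0, td, tc, division_times)
}

#' Per-division growth metrics of one cell
#'
#' Generation times (time between successive divisions), growth per cycle
#' (relative size increase between successive division sizes, the first
#' relative to the size at birth) and cumulative growth (size at death over
#' size at birth).
#'
#' @param table A `lineage_table`.
#' @param cell_id One cell id.
#' @return List with `generation_times`, `growth_per_cycle` (both length
#'   `rls`) and `cumulative_growth`.
#' @export
growth_metrics <- function(table, cell_id) {
  cells <- table$cells
  r <- match(cell_id, cells$cell_id)
  if (is.na(r)) stop("unknown cell id")
  if (cells$censored[r]) stop("growth metrics are undefined for censored cells")
  dt <- cells$division_times[[r]]
  sizes <- c(cells$S0[r], cells$sizes_at_divisions[[r]])
  list(generation_times = diff(c(cells$t0[r], dt)),
       growth_per_cycle = if (length(dt) == 0) numeric(0) else
         sizes[-1] / sizes[-length(sizes)],
       cumulative_growth = cells$size_at_end[r] / cells$S0[r])
}

#' Per-cell metric table
#'
#' Computes every single-cell property for each cell in the table: replicative
#' lifespan, lifetime, mean generation time, mean growth per cycle, cumulative
#' growth, health span, rejuvenation index (NA for founders), damage and size
#' at birth, generation and the first two lineage-position indices. Censored
#' cells keep their identifiers but carry NA for lifespan-based metrics.
#'
#' @param table A `lineage_table`.
#' @param mean_rls Average replicative lifespan used to scale the rejuvenation
#'   index; by default the mean over uncensored cells (founders included).
#' @return A data.frame keyed by `cell_id`.
#' @export
cell_metrics <- function(table, mean_rls = NULL) {
  cells <- table$cells
  unc <- !cells$censored
  if (is.null(mean_rls)) {
    if (!any(unc)) stop("no uncensored cells: metrics undefined")
    mean_rls <- mean(cells$rls[unc])
  }
  n <- nrow(cells)
  h <- rep(NA_real_, n)
  h[unc] <- health_span(table, cells$cell_id[unc])
  mgt <- mgpc <- cg <- rep(NA_real_, n)
  for (r in which(unc)) {
    gm <- growth_metrics(table, cells$cell_id[r])
    mgt[r] <- if (length(gm$generation_times)) mean(gm$generation_times) else NA
    mgpc[r] <- if (length(gm$growth_per_cycle)) mean(gm$growth_per_cycle) else NA
    cg[r] <- gm$cumulative_growth
  }
  mrow <- match(cells$mother_id, cells$cell_id)
  rls_mother <- cells$rls[mrow]
  rej <- rep(NA_real_, n)
  ok <- !is.na(mrow) & unc & !cells$censored[ifelse(is.na(mrow), 1L, mrow)]
  if (mean_rls > 0)
    rej[ok] <- (cells$rls[ok] - rls_mother[ok]) / mean_rls
  ij <- t(vapply(cells$position, function(p) {
    v <- position_indices(p)
    c(if (length(v) >= 1) v[1] else NA_integer_,
      if (length(v) >= 2) v[2] else NA_integer_)
  }, integer(2)))
  data.frame(cell_id = cells$cell_id, generation = cells$generation,
             i = ij[, 1], j = ij[, 2], censored = cells$censored,
             rls = ifelse(unc, cells$rls, NA_integer_),
             lifetime = cells$td - cells$t0,
             mean_generation_time = mgt, mean_growth_per_cycle = mgpc,
             cumulative_growth = cg, health_span = h,
             rejuvenation_index = rej,
             damage_at_birth = cells$D0, size_at_birth = cells$S0,
             row.names = NULL)
}

#' Population-level summary
#'
#' Box-score of a lineage: number of cells born, mean and standard deviation
#' of the replicative lifespan over uncensored cells, fraction of rejuvenated
#' cells (rejuvenation index > 0, over uncensored non-founders), fraction of
#' healthy cells (health span > `h_c`, over uncensored cells) and the
#' growth-rate proxy (number of cells born by `snapshot_time`).
#'
#' @param table A `lineage_table`.
#' @param h_c Healthy-cell cutoff on the health span (default 0.5).
#' @param snapshot_time Time point of the growth proxy (default 8).
#' @return A one-row data.frame.
#' @export
population_summary <- function(table, h_c = 0.5, snapshot_time = 8) {
  cells <- table$cells
  unc <- !cells$censored
  nonf <- !is.na(cells$mother_id)
  if (!any(unc & nonf))
    stop("no uncensored non-founder cells: population fractions undefined")
  m <- cell_metrics(table)
  rej <- m$rejuvenation_index[unc & nonf]
  rej <- rej[!is.na(rej)]
  if (length(rej) == 0)
    stop("no cells with a defined rejuvenation index")
  data.frame(
    population_size = nrow(cells),
    n_uncensored = sum(unc),
    mean_rls = mean(cells$rls[unc]),
    sd_rls = stats::sd(cells$rls[unc]),
    fraction_rejuvenated = mean(rej > 0),
    fraction_healthy = mean(m$health_span[unc] > h_c),
    cells_born_by_snapshot = sum(cells$t0 <= snapshot_time),
    row.names = NULL)
}

#' Aggregate cell metrics by lineage position (grandmother grid)
#'
#' Groups cells by the first two lineage-position indices: generation >= 2
#' cells on the `(i, j)` grid (the cell is the i-th daughter of its mother,
#' which is the j-th daughter of the grandmother), generation-1 cells by `i`
#' alone (`j = NA`). Founders are excluded; empty groups are omitted.
#'
#' @param table A `lineage_table`.
#' @param metrics Character vector of [cell_metrics()] columns to aggregate.
#' @return Long-format data.frame with columns `i`, `j`, `metric`, `n`,
#'   `mean`, `sd`.
#' @export
group_by_lineage_position <- function(table,
                                      metrics = c("rls", "health_span",
                                                  "rejuvenation_index",
                                                  "mean_generation_time",
                                                  "damage_at_birth",
                                                  "size_at_birth")) {
  m <- cell_metrics(table)
  m <- m[m$generation >= 1 & !m$censored, , drop = FALSE]
  if (nrow(m) == 0) return(data.frame(i = integer(0), j = integer(0),
                                      metric = character(0), n = integer(0),
                                      mean = numeric(0), sd = numeric(0)))
  key <- paste(m$i, m$j, sep = "/")
  out <- do.call(rbind, lapply(split(m, key), function(g) {
    do.call(rbind, lapply(metrics, function(f) {
      v <- g[[f]]
      v <- v[!is.na(v)]
      if (length(v) == 0) return(NULL)
      data.frame(i = g$i[1], j = g$j[1], metric = f, n = length(v),
                 mean = mean(v), sd = stats::sd(v))
    }))
  }))
  rownames(out) <- NULL
  out[order(out$metric, out$i, out$j), , drop = FALSE]
}
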