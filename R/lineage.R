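#' Mixed-effects specification for cell-to-cell variability
#'
#' Population fixed effects for the damage formation and repair rates plus the
#' standard deviation of the log-scale random effects. Each newborn cell draws
#' `k1 = k1_bar * exp(eta1)` and `k2 = k2_bar * exp(eta2)` with independent
#' `eta ~ N(0, sigma^2)`; the log-normal map guarantees strictly positive
#' rates.
#'
#' @param k1_bar,k2_bar Population fixed effects, > 0.
#' @param sigma Standard deviation of the random effects, >= 0.
#' @return An object of class `mixed_effects_spec`.
#' @export
mixed_effects_spec <- function(k1_bar, k2_bar, sigma = 0) {
  if (k1_bar <= 0 || k2_bar <= 0) stop("k1_bar and k2_bar must be > 0")
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(k1_bar = k1_bar, k2_bar = k2_bar, sigma = sigma),
            class = "mixed_effects_spec")
}

#' Sample individual rate parameters
#'
#' Draws `n` pairs `(k1, k2)` from the mixed-effects model using the current
#' RNG stream. With `sigma = 0` the fixed effects are returned exactly.
#'
#' @param spec A [mixed_effects_spec()].
#' @param n Number of pairs to draw.
#' @return A two-column matrix with columns `k1`, `k2`; all entries > 0.
#' @export
sample_cell_parameters <- function(spec, n = 1L) {
  if (spec$sigma == 0) {
    return(cbind(k1 = rep(spec$k1_bar, n), k2 = rep(spec$k2_bar, n)))
  }
  eta1 <- stats::rnorm(n, 0, spec$sigma)
  eta2 <- stats::rnorm(n, 0, spec$sigma)
  cbind(k1 = spec$k1_bar * exp(eta1), k2 = spec$k2_bar * exp(eta2))
}

# 32-bit FNV-1a hash of a key string, folded into a valid set.seed() value.
# Per-cell substreams are keyed by (root seed, founder, lineage position) so
# that a cell's random effects do not depend on traversal order or on how
# many cells were simulated before it, and matched arms of an experiment
# (e.g. stressed vs unstressed) draw identical effects for identical
# positions (common random numbers).
.key_hash <- function(seed, key) {
  h <- 17
  for (b in utf8ToInt(paste0(seed, "|", key))) {
    h <- (h * 131 + b) %% 2147483647
  }
  as.integer(h)
}

# draw (k1, k2) for one cell from its keyed substream, preserving the caller's
# RNG state
.sample_for_cell <- function(spec, seed, key) {
  if (spec$sigma == 0) return(c(k1 = spec$k1_bar, k2 = spec$k2_bar))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.key_hash(seed, key))
  drop(sample_cell_parameters(spec, 1L))
}

#' Grow a cell population from founder cells
#'
#' Recursively builds the lineage: every newborn cell is simulated with
#' [simulate_cell()] under its own sampled `(k1, k2)`, each daughter is
#' enqueued at her birth time with her lineage position, and the complete
#' pedigree is returned. Internally a birth-time-ordered queue replaces
#' literal recursion; the output is identical. Two stopping modes are
#' supported: a generation cap (daughters beyond `max_generation` are not
#' spawned) and an absolute time horizon `t_max` (cells alive at the horizon
#' are censored, spawning is complete up to the horizon).
#'
#' @param params A `cell_params`; its `k1`, `k2` act as the population fixed
#'   effects, all other entries are shared by every cell.
#' @param n_founders Number of founder cells (ignored if `founders` given).
#' @param founders Optional list of `cell_state` birth states; defaults to
#'   `n_founders` copies of [founder_state()] with damage `founder_D0`.
#' @param sigma Mixed-effects standard deviation (see [mixed_effects_spec()]).
#' @param seed Root RNG seed (integer). Identical `(seed, config)` give
#'   identical tables.
#' @param max_generation Generation cap; founders are generation 0.
#' @param max_cells Cap on the number of cells born; when reached, no further
#'   daughters are enqueued and the table is flagged `truncated`.
#' @param t_max Optional absolute time horizon (default `Inf` = generation-cap
#'   mode only).
#' @param founder_D0 Damage at birth of the default founders.
#' @param max_divisions,max_lifetime Per-cell caps passed to [simulate_cell()].
#' @param stress_multiplier Factor applied to the `k1` fixed effect (stress =
#'   increased damage formation); random effects are unaffected, so matched
#'   seeds give common random numbers across stress arms.
#' @param progress If `TRUE`, log births/deaths per generation to stderr.
#' @return A `lineage_table`: list with `cells` (one row per cell; columns
#'   include ids, lineage position, birth/death times, sampled rates, and
#'   list-columns `division_times`, `d_at_divisions`, `sizes_at_divisions`),
#'   `founders`, `seed`, `config`, `truncated`.
#' @export
run_population <- function(params, n_founders = 1L, founders = NULL,
                           sigma = 0, seed = 1L, max_generation = 2L,
                           max_cells = 5000L, t_max = Inf, founder_D0 = 0,
                           max_divisions = 1000L, max_lifetime = 1e4,
                           stress_multiplier = 1, progress = FALSE) {
  stopifnot(max_generation >= 0, max_cells >= 1)
  seed <- as.integer(seed)
  max_generation <- as.integer(max_generation)
  max_cells <- as.integer(max_cells)
  max_divisions <- as.integer(max_divisions)
  if (is.null(founders)) {
    if (n_founders < 1) stop("need at least one founder")
    founders <- replicate(n_founders,
                          founder_state(params, D0 = founder_D0),
                          simplify = FALSE)
  }
  n_founders <- length(founders)
  spec <- mixed_effects_spec(params$k1 * stress_multiplier, params$k2, sigma)

  # pending queue (parallel vectors)
  q_t0 <- vapply(founders, `[[`, numeric(1), "t")
  q_state <- founders
  q_mother <- rep(NA_integer_, n_founders)
  q_pos <- rep("", n_founders)
  q_founder <- seq_len(n_founders)
  q_gen <- rep(0L, n_founders)
  born <- n_founders
  truncated <- FALSE

  recs <- list()
  next_id <- 0L
  while (length(q_t0) > 0) {
    # deterministic order: earliest birth, ties by enqueue order
    i <- which.min(q_t0)
    st <- q_state[[i]]
    mother <- q_mother[i]
    pos <- q_pos[i]
    fndr <- q_founder[i]
    gen <- q_gen[i]
    q_t0 <- q_t0[-i]; q_state <- q_state[-i]; q_mother <- q_mother[-i]
    q_pos <- q_pos[-i]; q_founder <- q_founder[-i]; q_gen <- q_gen[-i]

    kk <- .sample_for_cell(spec, seed, paste0("f", fndr, "|", pos))
    p_cell <- params
    p_cell$k1 <- kk[["k1"]]
    p_cell$k2 <- kk[["k2"]]
    life_cap <- if (is.finite(t_max))
                  max(min(max_lifetime, t_max - st$t), 1e-9)
                else max_lifetime
    frag <- simulate_cell(st, p_cell, max_divisions = max_divisions,
                          max_lifetime = life_cap)
    id <- next_id
    next_id <- next_id + 1L
    recs[[id + 1L]] <- list(cell_id = id, mother_id = mother, position = pos,
                            generation = gen, founder = fndr, t0 = st$t,
                            td = frag$td, t_end = frag$state_at_end$t,
                            censored = frag$censored, P0 = st$P, D0 = st$D,
                            S0 = st$P + params$Q * st$D,
                            k1 = kk[["k1"]], k2 = kk[["k2"]], rls = frag$rls,
                            t_health = frag$t_health,
                            size_at_end = frag$size_at_end,
                            division_times = frag$division_times,
                            d_at_divisions = frag$d_at_divisions,
                            sizes_at_divisions = frag$sizes_at_divisions)
    if (progress) {
      message(sprintf("cell %d gen %d pos '%s': rls %d %s", id, gen, pos,
                      frag$rls,
                      if (frag$censored) "(censored)" else
                        sprintf("died at %.4g", frag$td)))
    }
    if (gen < max_generation && length(frag$daughters) > 0) {
      for (n in seq_along(frag$daughters)) {
        if (born >= max_cells) { truncated <- TRUE; break }
        d <- frag$daughters[[n]]
        if (is.finite(t_max) && d$t > t_max) next
        q_t0 <- c(q_t0, d$t)
        q_state <- c(q_state, list(d))
        q_mother <- c(q_mother, id)
        q_pos <- c(q_pos, if (pos == "") as.character(n)
                          else paste0(n, ".", pos))
        q_founder <- c(q_founder, fndr)
        q_gen <- c(q_gen, gen + 1L)
        born <- born + 1L
      }
    }
  }

  cells <- .records_to_df(recs)
  structure(list(cells = cells,
                 founders = cells$cell_id[is.na(cells$mother_id)],
                 seed = seed,
                 config = list(params = params, sigma = sigma,
                               n_founders = n_founders,
                               founder_D0 = founder_D0,
                               max_generation = max_generation,
                               max_cells = max_cells, t_max = t_max,
                               max_divisions = max_divisions,
                               max_lifetime = max_lifetime,
                               stress_multiplier = stress_multiplier),
                 truncated = truncated),
            class = "lineage_table")
}

.records_to_df <- function(recs) {
  scalar <- c("cell_id", "mother_id", "position", "generation", "founder",
              "t0", "td", "t_end", "censored", "P0", "D0", "S0", "k1", "k2",
              "rls", "t_health", "size_at_end")
  cols <- lapply(scalar, function(f) unlist(lapply(recs, `[[`, f)))
  names(cols) <- scalar
  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  df$division_times <- lapply(recs, `[[`, "division_times")
  df$d_at_divisions <- lapply(recs, `[[`, "d_at_divisions")
  df$sizes_at_divisions <- lapply(recs, `[[`, "sizes_at_divisions")
  df
}

#' @export
print.lineage_table <- function(x, ...) {
  cat(sprintf(
    "<lineage_table> %d cells (%d founders), generations 0..%d, seed %s%s\n",
    nrow(x$cells), length(x$founders), max(x$cells$generation), x$seed,
    if (isTRUE(x$truncated)) " [truncated at cell cap]" else ""))
  cat(sprintf("  uncensored: %d; births span t = %.4g .. %.4g\n",
              sum(!x$cells$censored), min(x$cells$t0), max(x$cells$t0)))
  invisible(x)
}

#' Lineage position of a cell
#'
#' Reconstructs the self-first list of 1-based birth-order indices
#' `{i, j, ...}` (the cell is the i-th daughter of its mother, which is the
#' j-th daughter of its own mother, ...) by walking mother links back to the
#' founder. The founder has the empty position and generation 0.
#'
#' @param cell_id Cell id.
#' @param table A `lineage_table`.
#' @return Integer vector of indices (length 0 for a founder).
#' @export
position_of <- function(cell_id, table) {
  cells <- table$cells
  row <- match(cell_id, cells$cell_id)
  if (is.na(row)) stop("cell ", cell_id, " not in table")
  idx <- integer(0)
  while (!is.na(cells$mother_id[row])) {
    mrow <- match(cells$mother_id[row], cells$cell_id)
    if (is.na(mrow)) stop("broken pedigree link at cell ", cells$cell_id[row])
    i <- which(abs(cells$division_times[[mrow]] - cells$t0[row]) < 1e-12)
    if (length(i) != 1L)
      stop("birth time of cell ", cells$cell_id[row],
           " does not match a division of its mother")
    idx <- c(idx, i)
    row <- mrow
  }
  idx
}

#' Generation of a cell (pedigree depth)
#'
#' @inheritParams position_of
#' @return Integer generation; equals the number of lineage-position indices.
#' @export
generation_of <- function(cell_id, table) {
  length(position_of(cell_id, table))
}

# parse a dot-joined position string into its integer indices
position_indices <- function(pos) {
  if (is.na(pos) || pos == "") return(integer(0))
  as.integer(strsplit(pos, ".", fixed = TRUE)[[1]])
}
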