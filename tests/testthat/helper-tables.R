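# Hand-built lineage tables with known values, for exercising the metric
# formulas independently of the simulator.

toy_cell <- function(cell_id, mother_id = NA_integer_, position = "",
                     t0 = 0, td = NA_real_, censored = FALSE,
                     P0 = 0.18, D0 = 0, S0 = NULL, k1 = 0.4, k2 = 0.138,
                     rls = NULL, t_health = NA_real_, size_at_end = 1,
                     division_times = numeric(0),
                     d_at_divisions = NULL, sizes_at_divisions = NULL,
                     Q = 0.478) {
  if (is.null(S0)) S0 <- P0 + Q * D0
  if (is.null(rls)) rls <- length(division_times)
  if (is.null(d_at_divisions)) d_at_divisions <- rep(0.1, length(division_times))
  if (is.null(sizes_at_divisions))
    sizes_at_divisions <- seq_along(division_times) + 1
  list(cell_id = as.integer(cell_id), mother_id = as.integer(mother_id),
       position = position, generation = length(position_indices_test(position)),
       founder = 1L, t0 = t0, td = td,
       t_end = if (is.na(td)) t0 + 1 else td, censored = censored,
       P0 = P0, D0 = D0, S0 = S0, k1 = k1, k2 = k2, rls = as.integer(rls),
       t_health = t_health, size_at_end = size_at_end,
       division_times = division_times, d_at_divisions = d_at_divisions,
       sizes_at_divisions = sizes_at_divisions)
}

position_indices_test <- function(pos) {
  if (is.na(pos) || pos == "") integer(0)
  else as.integer(strsplit(pos, ".", fixed = TRUE)[[1]])
}

toy_table <- function(cells, params = wildtype_params("decline"), seed = 1L) {
  scalar <- c("cell_id", "mother_id", "position", "generation", "founder",
              "t0", "td", "t_end", "censored", "P0", "D0", "S0", "k1", "k2",
              "rls", "t_health", "size_at_end")
  cols <- lapply(scalar, function(f) unlist(lapply(cells, `[[`, f)))
  names(cols) <- scalar
  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  df$division_times <- lapply(cells, `[[`, "division_times")
  df$d_at_divisions <- lapply(cells, `[[`, "d_at_divisions")
  df$sizes_at_divisions <- lapply(cells, `[[`, "sizes_at_divisions")
  structure(list(cells = df,
                 founders = df$cell_id[is.na(df$mother_id)],
                 seed = seed,
                 config = list(params = params, sigma = 0, n_founders = 1L,
                               founder_D0 = 0, max_generation = 2L,
                               max_cells = 100L, t_max = Inf,
                               max_divisions = 1000L, max_lifetime = 1e4,
                               stress_multiplier = 1),
                 truncated = FALSE),
            class = "lineage_table")
}

# small simulated wildtype table, shared within a test file
small_wt_table <- function(regime = "decline", seed = 5L, n_founders = 2L,
                           max_generation = 1L, sigma = 0.005) {
  run_population(wildtype_params(regime), n_founders = n_founders,
                 sigma = sigma, seed = seed, max_generation = max_generation)
}
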