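# Lineage table I/O: a delimited per-cell table (full double precision, so the
# round trip through read_lineage() is lossless), a Newick tree whose labels
# are cell ids and whose branch lengths are lifetimes, and a JSON run manifest
# carrying the seed and config snapshot.

.fmt17 <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

.join_num <- function(lst) {
  vapply(lst, function(v) paste(.fmt17(v), collapse = ";"), character(1))
}

.split_num <- function(s) {
  lapply(s, function(v) if (is.na(v) || v == "") numeric(0)
         else as.numeric(strsplit(v, ";", fixed = TRUE)[[1]]))
}

#' Export a lineage table
#'
#' Writes three files next to `basename`: `<basename>.csv` (one row per cell,
#' comma-separated, header row, `.` decimal, UTF-8; per-division lists joined
#' with `;` and the lineage position as a dot-joined string), `<basename>.nwk`
#' (Newick, one tree per founder, labels `c<cell_id>`, branch lengths =
#' lifetimes, censored cells marked with a `[&censored]` comment) and
#' `<basename>_manifest.json` (seed, config snapshot, truncation flag).
#' [read_lineage()] restores the table losslessly.
#'
#' @param table A `lineage_table`.
#' @param basename Output path prefix (directories must exist).
#' @return `basename`, invisibly.
#' @export
export_lineage <- function(table, basename) {
  cells <- table$cells
  df <- data.frame(
    cell_id = cells$cell_id, mother_id = cells$mother_id,
    position = cells$position, generation = cells$generation,
    founder = cells$founder,
    t0 = .fmt17(cells$t0), td = .fmt17(cells$td), t_end = .fmt17(cells$t_end),
    censored = cells$censored,
    P0 = .fmt17(cells$P0), D0 = .fmt17(cells$D0), S0 = .fmt17(cells$S0),
    k1 = .fmt17(cells$k1), k2 = .fmt17(cells$k2), rls = cells$rls,
    t_health = .fmt17(cells$t_health), size_at_end = .fmt17(cells$size_at_end),
    division_times = .join_num(cells$division_times),
    d_at_divisions = .join_num(cells$d_at_divisions),
    sizes_at_divisions = .join_num(cells$sizes_at_divisions),
    stringsAsFactors = FALSE)
  csv <- paste0(basename, ".csv")
  tryCatch(utils::write.csv(df, csv, row.names = FALSE, quote = TRUE,
                            fileEncoding = "UTF-8"),
           error = function(e) stop("cannot write ", csv, ": ",
                                    conditionMessage(e)))
  writeLines(lineage_newick(table), paste0(basename, ".nwk"))
  manifest <- .config_manifest(table)
  jsonlite::write_json(manifest, paste0(basename, "_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(basename)
}

.config_manifest <- function(table) {
  cfg <- table$config
  p <- cfg$params
  # doubles are encoded as %.17g strings so the JSON round trip is lossless
  enc <- function(v) if (is.finite(v)) sprintf("%.17g", v) else "inf"
  list(seed = table$seed, truncated = table$truncated,
       founders = table$founders,
       version = as.character(utils::packageVersion("rejuvasim")),
       params = lapply(unclass(p), enc),
       sigma = enc(cfg$sigma), n_founders = cfg$n_founders,
       founder_D0 = enc(cfg$founder_D0),
       max_generation = cfg$max_generation,
       max_cells = cfg$max_cells, t_max = enc(cfg$t_max),
       max_divisions = cfg$max_divisions,
       max_lifetime = enc(cfg$max_lifetime),
       stress_multiplier = enc(cfg$stress_multiplier))
}

#' Read a lineage table written by [export_lineage()]
#'
#' @param basename The path prefix used at export time.
#' @return A `lineage_table`, equal to the exported one.
#' @export
read_lineage <- function(basename) {
  csv <- paste0(basename, ".csv")
  df <- utils::read.csv(csv, stringsAsFactors = FALSE,
                        colClasses = c(position = "character"),
                        na.strings = "NA")
  man <- jsonlite::read_json(paste0(basename, "_manifest.json"),
                             simplifyVector = TRUE)
  num <- function(x) as.numeric(x)
  cells <- data.frame(
    cell_id = as.integer(df$cell_id), mother_id = as.integer(df$mother_id),
    position = ifelse(is.na(df$position), "", df$position),
    generation = as.integer(df$generation), founder = as.integer(df$founder),
    t0 = num(df$t0), td = num(df$td), t_end = num(df$t_end),
    censored = as.logical(df$censored),
    P0 = num(df$P0), D0 = num(df$D0), S0 = num(df$S0),
    k1 = num(df$k1), k2 = num(df$k2), rls = as.integer(df$rls),
    t_health = num(df$t_health), size_at_end = num(df$size_at_end),
    stringsAsFactors = FALSE)
  cells$division_times <- .split_num(df$division_times)
  cells$d_at_divisions <- .split_num(df$d_at_divisions)
  cells$sizes_at_divisions <- .split_num(df$sizes_at_divisions)
  p <- man$params
  unstr <- function(v) if (identical(v, "inf")) Inf else as.numeric(v)
  params <- cell_params(g = unstr(p$g), k1 = unstr(p$k1), k2 = unstr(p$k2),
                        Q = unstr(p$Q), R = unstr(p$R), re = unstr(p$re),
                        s = unstr(p$s), P_div = unstr(p$P_div),
                        D_death = unstr(p$D_death),
                        D_health = unstr(p$D_health))
  structure(list(cells = cells,
                 founders = as.integer(man$founders),
                 seed = as.integer(man$seed),
                 config = list(params = params, sigma = unstr(man$sigma),
                               n_founders = as.integer(man$n_founders),
                               founder_D0 = unstr(man$founder_D0),
                               max_generation = as.integer(man$max_generation),
                               max_cells = as.integer(man$max_cells),
                               t_max = unstr(man$t_max),
                               max_divisions = as.integer(man$max_divisions),
                               max_lifetime = unstr(man$max_lifetime),
                               stress_multiplier = unstr(man$stress_multiplier)),
                 truncated = man$truncated),
            class = "lineage_table")
}

#' Newick representation of a lineage table
#'
#' Each cell is a node labelled `c<cell_id>`; its branch length is its
#' lifetime (time from birth to death, or to the censoring time for censored
#' cells, which additionally carry a `[&censored]` comment). Daughters are a
#' cell's children, ordered by birth. One tree per founder.
#'
#' @param table A `lineage_table`.
#' @return Character vector of Newick strings, one per founder.
#' @export
lineage_newick <- function(table) {
  cells <- table$cells
  kids <- split(seq_len(nrow(cells)), match(cells$mother_id, cells$cell_id))
  node <- function(row) {
    id <- cells$cell_id[row]
    ch <- kids[[as.character(row)]]
    ch <- ch[order(cells$t0[ch])]
    lt <- cells$t_end[row] - cells$t0[row]
    lab <- paste0("c", id, if (cells$censored[row]) "[&censored]" else "",
                  ":", sprintf("%.10g", lt))
    if (is.null(ch) || length(ch) == 0) return(lab)
    paste0("(", paste(vapply(ch, node, character(1)), collapse = ","), ")",
           lab)
  }
  vapply(which(is.na(cells$mother_id)), function(r) paste0(node(r), ";"),
         character(1))
}
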