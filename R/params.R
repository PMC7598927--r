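#' Model parameters for one cell's dynamics
#'
#' Bundles every rate and partition constant of the non-dimensionalised
#' single-cell damage-accumulation model and validates the domain constraints:
#' the growth factor `g`, damage formation rate `k1`, damage repair rate `k2`,
#' resilience to damage `Q` (weight of damaged protein in the size term
#' `S = P + Q*D`), repair capacity `R` (in `[1/pi, Inf]`; `Inf` gives linear,
#' damage-proportional repair), retention factor `re`, size proportion `s`
#' kept by the mother at division, and the three thresholds: `P_div`
#' (functional-protein level triggering division), `D_death` (damage level
#' triggering death) and `D_health` (damage threshold for health-span
#' accounting).
#'
#' @param g Growth factor, dimensionless rate, > 0.
#' @param k1 Damage formation rate, >= 0.
#' @param k2 Damage repair rate, >= 0.
#' @param Q Resilience to damage, >= 0.
#' @param R Repair capacity, in `[1/pi, Inf]`. `Inf` is a valid sentinel for
#'   unlimited capacity (repair flux exactly `k2*D`).
#' @param re Retention factor in `[0, 1]`.
#' @param s Size proportion kept by the mother at division, in `(0, 1)`.
#' @param P_div Critical functional-protein level triggering division.
#' @param D_death Critical damage level triggering death, <= 1.
#' @param D_health Damage threshold for the health span, `0 < D_health <= D_death`.
#' @return An object of class `cell_params` (a validated named list).
#' @seealso [wildtype_params()] for the shipped calibrated defaults.
#' @export
cell_params <- function(g, k1, k2, Q, R = Inf, re = 0, s = 0.64,
                        P_div = 1, D_death = 1, D_health = 0.5) {
  p <- list(g = g, k1 = k1, k2 = k2, Q = Q, R = R, re = re, s = s,
            P_div = P_div, D_death = D_death, D_health = D_health)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
  for (nm in names(p)) {
    if (!num1(p[[nm]])) stop("parameter '", nm, "' must be a single number")
  }
  if (p$g <= 0) stop("g must be > 0")
  if (p$k1 < 0 || p$k2 < 0) stop("k1 and k2 must be >= 0")
  if (p$Q < 0) stop("Q must be >= 0")
  if (p$R < 1 / pi) stop("repair capacity R must be >= 1/pi (Inf allowed)")
  if (p$re < 0 || p$re > 1) stop("retention factor re must lie in [0, 1]")
  if (p$s <= 0 || p$s >= 1) stop("size proportion s must lie in (0, 1)")
  if (p$P_div <= 0) stop("P_div must be > 0")
  if (p$D_death <= 0 || p$D_death > 1) stop("D_death must lie in (0, 1]")
  if (p$D_health <= 0 || p$D_health > p$D_death)
    stop("D_health must satisfy 0 < D_health <= D_death")
  structure(p, class = "cell_params")
}

#' @export
print.cell_params <- function(x, ...) {
  cat("<cell_params>\n")
  vals <- vapply(x, function(v) format(v, digits = 6), character(1))
  cat(paste0("  ", format(names(x), width = 9), " ", vals, collapse = "\n"), "\n")
  invisible(x)
}

#' Shipped wildtype parameter set
#'
#' Returns the repository's calibrated non-dimensional base configuration: the
#' growth factor, resilience and division threshold are repository calibration
#' choices fixed so that a damage-free founder at the wildtype anchor point
#' (`k1 = 0.4`, `re = 0.2957`, with `k2 = 0.138` under declining repair
#' capacity and `k2 = 0.092` under unlimited capacity) completes exactly the
#' wildtype replicative lifespan of 24 divisions in both capacity regimes.
#'
#' @param regime `"decline"` (`R = 1/pi`) or `"unlimited"` (`R = Inf`).
#' @param re Retention factor, default the wildtype value 0.2957.
#' @param k1 Damage formation rate, default 0.4.
#' @param k2 Damage repair rate; defaults to the regime's wildtype value
#'   (0.138 for decline, 0.092 for unlimited).
#' @return A `cell_params` object.
#' @export
wildtype_params <- function(regime = c("decline", "unlimited"),
                            re = 0.2957, k1 = 0.4, k2 = NULL) {
  regime <- match.arg(regime)
  base <- wildtype_base()
  if (is.null(k2)) k2 <- if (regime == "decline") 0.138 else 0.092
  cell_params(g = base$g, k1 = k1, k2 = k2, Q = base$Q,
              R = if (regime == "decline") 1 / pi else Inf,
              re = re, s = base$s, P_div = base$P_div,
              D_death = base$D_death, D_health = base$D_health)
}

# Repository base calibration (see the methods vignette for how these were
# fixed). Single source of truth for the non-dimensional base values.
wildtype_base <- function() {
  list(g = 1.92, Q = 0.478, s = 0.64, P_div = 0.5, D_death = 1, D_health = 0.5)
}

#' Average initial conditions for a founder cell
#'
#' A founder is initialised as the newborn of an average division: functional
#' protein `(1 - s) * P_div` and, by default, no damage.
#'
#' @param params A `cell_params` object.
#' @param D0 Damage at birth (default 0, a damage-free founder).
#' @param t0 Birth time.
#' @return A `cell_state` list with fields `t`, `P`, `D`.
#' @export
founder_state <- function(params, D0 = 0, t0 = 0) {
  cell_state(t = t0, P = (1 - params$s) * params$P_div, D = D0)
}

#' Instantaneous cell state
#'
#' @param t Dimensionless time.
#' @param P Functional protein content, >= 0.
#' @param D Damaged protein content, in `[0, 1]`.
#' @return An object of class `cell_state`.
#' @export
cell_state <- function(t, P, D) {
  if (P < 0) stop("P must be >= 0")
  if (D < 0 || D > 1) stop("D must lie in [0, 1]")
  structure(list(t = t, P = P, D = D), class = "cell_state")
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf("<cell_state> t = %g, P = %g, D = %g\n", x$t, x$P, x$D))
  invisible(x)
}

#' Read a model configuration file
#'
#' Configurations are YAML with keys named exactly after the [cell_params()]
#' fields, plus optional `sigma` (mixed-effects standard deviation), founder
#' and cap settings. The string `"inf"` (any case) encodes an infinite repair
#' capacity.
#'
#' @param path Path to a YAML configuration file.
#' @return A list with elements `params` (a `cell_params`), `sigma`,
#'   `founders`, `founder_D0`, `max_generation`, `max_cells`,
#'   `max_divisions`, `max_lifetime`, `target_rls`.
#' @export
read_model_config <- function(path) {
  raw <- yaml::read_yaml(path)
  need <- c("g", "k1", "k2", "Q", "R", "re", "s", "P_div", "D_death", "D_health")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0)
    stop("config is missing keys: ", paste(miss, collapse = ", "))
  Rval <- raw$R
  if (is.character(Rval)) {
    if (tolower(Rval) %in% c("inf", "infinity")) Rval <- Inf
    else Rval <- as.numeric(Rval)
  }
  params <- cell_params(g = raw$g, k1 = raw$k1, k2 = raw$k2, Q = raw$Q,
                        R = Rval, re = raw$re, s = raw$s, P_div = raw$P_div,
                        D_death = raw$D_death, D_health = raw$D_health)
  pick <- function(key, default) if (is.null(raw[[key]])) default else raw[[key]]
  list(params = params,
       sigma = pick("sigma", 0),
       founders = pick("founders", 1L),
       founder_D0 = pick("founder_D0", 0),
       max_generation = pick("max_generation", 2L),
       max_cells = pick("max_cells", 5000L),
       max_divisions = pick("max_divisions", 1000L),
       max_lifetime = pick("max_lifetime", 1e4),
       target_rls = pick("target_rls", 24L))
}

#' Write a model configuration file
#'
#' Inverse of [read_model_config()]; infinite repair capacity is written as
#' the literal string `"inf"`.
#'
#' @param config A list as returned by [read_model_config()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(config, path) {
  p <- config$params
  out <- list(g = p$g, k1 = p$k1, k2 = p$k2, Q = p$Q,
              R = if (is.finite(p$R)) p$R else "inf",
              re = p$re, s = p$s, P_div = p$P_div,
              D_death = p$D_death, D_health = p$D_health,
              sigma = config$sigma, founders = config$founders,
              founder_D0 = config$founder_D0,
              max_generation = config$max_generation,
              max_cells = config$max_cells,
              max_divisions = config$max_divisions,
              max_lifetime = config$max_lifetime,
              target_rls = config$target_rls)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Path to the shipped wildtype configuration
#'
#' @param regime `"decline"` or `"unlimited"`.
#' @return Path to the installed YAML configuration.
#' @export
wildtype_config_path <- function(regime = c("decline", "unlimited")) {
  regime <- match.arg(regime)
  system.file("extdata", paste0("wildtype_", regime, ".yaml"),
              package = "rejuvasim", mustWork = TRUE)
}
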