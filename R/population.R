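# Stochastic population simulation: initialization from the stem basin,
# Gillespie channel primitives, division with binomial partitioning, and the
# population SSA driver (C++ engine).

#' Population simulation configuration
#'
#' @param n_populations number of independent replicate populations.
#' @param cells_per_population founding stem cells per population.
#' @param preset switch preset name (see [switch_preset()]); ignored when
#'   `params` is given.
#' @param seed integer seed for all randomness of the run.
#' @param duration simulated time per run; defaults to one cell-cycle time T.
#' @param population_cap hard cap on cells per population; runs that reach it
#'   return with a `capped` flag.
#' @param params optional explicit [switch_params()] overriding the preset.
#' @return An object of class `population_config`.
#' @export
population_config <- function(n_populations = 1000L, cells_per_population = 50L,
                              preset = "two-element", seed = 1L,
                              duration = NULL, population_cap = 1000L,
                              params = NULL) {
  n_populations <- as.integer(n_populations)
  cells_per_population <- as.integer(cells_per_population)
  population_cap <- as.integer(population_cap)
  if (n_populations < 1L || cells_per_population < 1L)
    stop("population and cell counts must be >= 1")
  if (population_cap < cells_per_population)
    stop("'population_cap' must be at least 'cells_per_population'")
  if (is.null(params)) params <- switch_preset(preset)
  if (!is.null(duration) && duration <= 0) stop("'duration' must be positive")
  structure(list(n_populations = n_populations,
                 cells_per_population = cells_per_population,
                 preset = attr(params, "preset"),
                 params = params, seed = as.integer(seed),
                 duration = duration, population_cap = population_cap),
            class = "population_config")
}

# integer-lattice basin raster (one grid cell per molecule), cached per preset
lattice_basin <- function(params) {
  key <- paste0("basin|", param_key(params))
  if (!is.null(.tristem_cache[[key]])) return(.tristem_cache[[key]])
  upper <- round(1.25 * steady_state_max(master_system(params)))
  bm <- basin_map(params, resolution = upper + 1L, upper = upper)
  .tristem_cache[[key]] <- bm
  bm
}

# labelled stable attractors of the full 2m-dimensional switch, cached
full_attractors <- function(params) {
  key <- paste0("fullattr|", param_key(params))
  if (!is.null(.tristem_cache[[key]])) return(.tristem_cache[[key]])
  at <- label_attractors(find_fixed_points(params))
  .tristem_cache[[key]] <- at
  at
}

#' Initialize a population of stem cells
#'
#' Draws `cells_per_population` integer states uniformly from the lattice
#' points of the stem (C) attractor basin of the master-pair plane; for
#' extended switches the support elements start at the middle attractor's
#' values rounded to integers. All founding cells carry the unmutated switch
#' parameters and fate C.
#'
#' @param config a [population_config()].
#' @param basin optional precomputed lattice-resolution [basin_map()];
#'   computed (and cached) from the config's parameters when omitted.
#' @param seed optional seed; when given, `set.seed(seed)` is called first.
#' @param fate_rule `"master"` (default): daughter fate from the master pair
#'   in the 2-D master-pair fate map; `"full"`: basin of the full
#'   2m-dimensional state (provided for comparison studies).
#' @return An object of class `cell_population`.
#' @examples \donttest{
#' cfg <- population_config(n_populations = 1, cells_per_population = 10)
#' pop <- init_population(cfg, seed = 1)
#' }
#' @export
init_population <- function(config, basin = NULL, seed = NULL,
                            fate_rule = c("master", "full")) {
  fate_rule <- match.arg(fate_rule)
  if (!is.null(seed)) set.seed(seed)
  params <- config$params
  m <- params$m
  if (is.null(basin)) basin <- lattice_basin(params)
  cidx <- which(basin$labels == "C", arr.ind = TRUE)
  if (nrow(cidx) == 0L) stop("stem basin (C) is empty at this resolution")
  n <- config$cells_per_population
  pick <- sample.int(nrow(cidx), n, replace = TRUE)
  states <- matrix(0L, n, 2L * m)
  states[, 1] <- as.integer(round(basin$x[cidx[pick, 1]]))
  states[, m + 1] <- as.integer(round(basin$y[cidx[pick, 2]]))
  if (m > 1L) {
    supp <- round(full_attractors(params)$C$location)
    for (i in seq_len(m)[-1]) {
      states[, i] <- as.integer(supp[i])
      states[, m + i] <- as.integer(supp[m + i])
    }
  }
  colnames(states) <- state_names(m)
  arow <- if (fate_rule == "master") attr_row(basin$attractors, 1L)
          else attr_row(full_attractors(params), m)
  structure(list(
    states = states,
    alphas = matrix(rep(alpha_vector(params), each = n), nrow = n),
    attr = matrix(rep(arow, each = n), nrow = n),
    counters = matrix(0, n, 6,
                      dimnames = list(NULL, c("divisions", "stem_daughters",
                                              "total_daughters", "ph_divisions",
                                              "ph_stem", "ph_total"))),
    lineage = seq_len(n), next_id = n + 1L,
    params = params, fate_rule = fate_rule, time = 0,
    T = cycle_time(params), cap = config$population_cap,
    flags = character(0),
    log = NULL, events = c(production = 0, degradation = 0, division = 0)
  ), class = "cell_population")
}

#' @export
print.cell_population <- function(x, ...) {
  cat(sprintf("cell_population: %d stem cell(s), t = %.3f (T = %.3f)\n",
              nrow(x$states), x$time, x$T))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Select a reaction channel from propensities
#'
#' Returns the channel index r satisfying
#' `S[r-1]/S < u1 <= S[r]/S` with `S[r]` the prefix sums of the channel
#' rates — the standard direct-method selection of the Gillespie algorithm.
#'
#' @param rates nonnegative channel propensities, at least one positive.
#' @param u1 a uniform variate in (0, 1).
#' @return The 1-based channel index.
#' @examples
#' select_reaction(c(1, 1), 0.25)  # 1
#' select_reaction(c(1, 1), 0.75)  # 2
#' @export
select_reaction <- function(rates, u1) {
  if (any(rates < 0) || !any(rates > 0)) stop("need nonnegative rates, at least one positive")
  if (u1 <= 0 || u1 >= 1) stop("'u1' must lie strictly in (0, 1)")
  findInterval(u1 * sum(rates), c(0, cumsum(rates)), left.open = TRUE,
               rightmost.closed = TRUE)
}

#' Waiting time to the next reaction
#'
#' `dt = ln(1/u2) / total_rate`, the exponential waiting time of the
#' Gillespie algorithm.
#'
#' @param total_rate sum of all propensities (> 0).
#' @param u2 uniform variate(s) in (0, 1]; vectorized.
#' @return The time increment(s).
#' @examples
#' waiting_time(2, exp(-2))  # 1
#' @export
waiting_time <- function(total_rate, u2) {
  if (length(total_rate) != 1L || total_rate <= 0)
    stop("'total_rate' must be a single positive rate")
  if (any(u2 <= 0 | u2 > 1)) stop("'u2' must lie in (0, 1]")
  log(1 / u2) / total_rate
}

#' Divide one cell with binomial partitioning
#'
#' Splits every determinant of the mother binomially (each molecule goes to
#' daughter 1 with probability 1/2, the remainder to daughter 2), classifies
#' both daughters by the attractor basin of the mother's own (possibly
#' mutated) switch parameters, and returns the daughters and a division
#' record. Determinants are conserved exactly: the two daughters' counts sum
#' to the mother's per element.
#'
#' @param state mother's integer determinant counts.
#' @param params the mother's [switch_params()] (inherited by both daughters).
#' @param fixed_points optional precomputed fixed points for the classifier.
#' @param time division time recorded in the record.
#' @param lineage mother lineage identifier for the record.
#' @return A list with `daughters` (2 x 2m matrix), `fates` (factor length
#'   2), and `record` (one-row data frame).
#' @export
divide_cell <- function(state, params, fixed_points = NULL, time = NA_real_,
                        lineage = NA_integer_) {
  state <- check_state(state, params, integer = TRUE)
  d1 <- rbinom(length(state), size = as.integer(state), prob = 0.5)
  d2 <- as.integer(state) - d1
  if (is.null(fixed_points)) fixed_points <- find_fixed_points(params)
  f1 <- classify_fate(d1, params, fixed_points)
  f2 <- classify_fate(d2, params, fixed_points)
  rec <- data.frame(time = time, mother = lineage,
                    daughter1_fate = as.character(f1),
                    daughter2_fate = as.character(f2))
  m <- params$m
  for (j in seq_len(2 * m)) {
    rec[[paste0("d1_", state_names(m)[j])]] <- d1[j]
    rec[[paste0("d2_", state_names(m)[j])]] <- d2[j]
  }
  list(daughters = rbind(d1, d2), fates = c(f1, f2), record = rec)
}

#' Enumerate the reaction channels of a population
#'
#' One production and one degradation channel per determinant per cell
#' (updating reactions, listed first, in cell insertion order), then one
#' division channel per cell. A 50-cell two-element population therefore has
#' 200 updating channels and 250 channels in total.
#'
#' @param pop a `cell_population`.
#' @return A data frame with one row per channel: `index`, `cell`, `kind`
#'   (`update`/`division`), `channel` (the per-cell channel name).
#' @export
enumerate_channels <- function(pop) {
  m <- pop$params$m
  n <- nrow(pop$states)
  per_cell <- c(paste0("prod_x", seq_len(m)), paste0("deg_x", seq_len(m)),
                paste0("prod_y", seq_len(m)), paste0("deg_y", seq_len(m)))
  upd <- data.frame(cell = rep(seq_len(n), each = 4 * m),
                    kind = "update", channel = rep(per_cell, n))
  div <- data.frame(cell = seq_len(n), kind = "division", channel = "division")
  out <- rbind(upd, div)
  out$index <- seq_len(nrow(out))
  out[, c("index", "cell", "kind", "channel")]
}

engine_log_to_df <- function(log, m) {
  nd <- length(log$time)
  if (nd == 0L) return(NULL)
  df <- data.frame(time = log$time, mother = log$mother,
                   daughter1_fate = as.character(decode_fates(log$fate1)),
                   daughter2_fate = as.character(decode_fates(log$fate2)))
  if (!is.null(log$counts1)) {
    for (j in seq_len(2 * m)) df[[paste0("d1_", state_names(m)[j])]] <- log$counts1[, j]
    for (j in seq_len(2 * m)) df[[paste0("d2_", state_names(m)[j])]] <- log$counts2[, j]
  }
  df
}

#' Run the exact stochastic simulation of one population
#'
#' Advances the population with the Gillespie algorithm: every cell
#' contributes one production and one degradation channel per determinant
#' plus a division channel at rate 1/T; after every event all of the affected
#' cell's propensities are recomputed. Divisions partition determinants
#' binomially, classify each daughter with the mother's own switch
#' parameters, keep stem daughters, and record-then-discard differentiated
#' daughters (differentiated cells die at birth). Runs stop at the time
#' horizon, or — under the `"divisions"` rule — as soon as every surviving
#' lineage has completed at least `k` divisions since the rule was armed
#' (with a time cap), or when the population goes extinct or hits the cap.
#'
#' @param pop a `cell_population` from [init_population()].
#' @param until stopping rule: `"time"` or `"divisions"`.
#' @param t duration for the `"time"` rule; defaults to one cycle T.
#' @param k required divisions per lineage for the `"divisions"` rule.
#' @param t_max time cap for the `"divisions"` rule; default `4 * T`.
#' @param division set `FALSE` to switch the division channel off (pure
#'   determinant kinetics).
#' @param record_counts record daughter determinant counts in the division
#'   log (on by default; turn off for large protocol runs).
#' @param radius,dt_ode classifier settings, see [classify_fate()].
#' @return The updated `cell_population`; `$log` holds the division log,
#'   `$events` the audit counts, and `$flags` any of `extinct`, `capped`,
#'   `rule_met`, `timed_out`.
#' @examples \donttest{
#' cfg <- population_config(n_populations = 1, cells_per_population = 10)
#' pop <- init_population(cfg, seed = 1)
#' pop <- run_population(pop)
#' scb_rate(pop$log)
#' }
#' @export
run_population <- function(pop, until = c("time", "divisions"), t = NULL,
                           k = 2L, t_max = NULL, division = TRUE,
                           record_counts = TRUE, radius = 1, dt_ode = 0.05) {
  until <- match.arg(until)
  params <- pop$params
  Tc <- pop$T
  horizon <- 10 * Tc
  t_end <- if (until == "time") pop$time + (if (is.null(t)) Tc else t)
           else pop$time + (if (is.null(t_max)) 4 * Tc else t_max)
  res <- cpp_pop_run(pop$states, pop$alphas, pop$attr, pop$counters,
                     as.integer(pop$lineage), as.integer(pop$next_id),
                     params$beta, params$n, params$gamma, params$m,
                     pop$time, t_end,
                     if (division) 1 / Tc else 0,
                     if (until == "divisions") 1L else 0L, as.integer(k),
                     as.integer(pop$cap), radius, horizon, dt_ode,
                     record_counts, identical(pop$fate_rule, "full"))
  pop$states <- res$states
  colnames(pop$states) <- state_names(params$m)
  pop$alphas <- res$alphas
  pop$attr <- res$attr
  pop$counters <- res$counters
  colnames(pop$counters) <- c("divisions", "stem_daughters", "total_daughters",
                              "ph_divisions", "ph_stem", "ph_total")
  pop$lineage <- res$lineage
  pop$next_id <- res$next_id
  pop$time <- res$time
  newlog <- engine_log_to_df(res$log, params$m)
  pop$log <- if (is.null(pop$log)) newlog else rbind(pop$log, newlog)
  pop$events <- pop$events + res$events
  flags <- c("extinct", "capped", "rule_met", "timed_out")
  pop$flags <- union(pop$flags, flags[unlist(res[flags])])
  pop$classify_warnings <- (pop$classify_warnings %||% 0L) + res$warnings
  pop
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stem-cell birth rate of a division log
#'
#' The fraction of all daughter cells in the log classified as stem (fate C):
#' the probability of generating a stem cell per division outcome. In
#' homeostasis this is 0.5 — symmetric differentiating (DD) and symmetric
#' self-renewing (SS) divisions balance.
#'
#' @param log a division log (`$log` of a run, or any data frame with
#'   `daughter1_fate`, `daughter2_fate`), or a list of such logs.
#' @return The pooled stem-daughter fraction.
#' @export
scb_rate <- function(log) {
  if (is.data.frame(log)) log <- list(log)
  log <- Filter(Negate(is.null), log)
  if (length(log) == 0L) stop("no divisions recorded: SCB rate undefined")
  fates <- unlist(lapply(log, function(l) c(l$daughter1_fate, l$daughter2_fate)))
  if (length(fates) == 0L) stop("no divisions recorded: SCB rate undefined")
  mean(fates == "C")
}

#' Run replicate homeostasis populations
#'
#' Initializes `n_populations` independent populations from the stem basin,
#' equilibrates each for `burnin` cell cycles so the determinant
#' distribution reaches the homeostatic stationary state (the
#' initialization draws cells uniformly over the stem domain, which decays
#' to the stationary distribution within about two cycles), then measures
#' one cycle (or `config$duration`). The pooled SCB rate is computed from
#' the divisions of the measurement window only.
#'
#' @param config a [population_config()].
#' @param burnin equilibration time before the measurement window, in cell
#'   cycles (default 2; set 0 to measure from the initial state).
#' @param record_counts keep daughter counts in the logs.
#' @return A list with `populations` (list of `cell_population`), `logs`
#'   (measurement-window division logs), pooled `scb`, per-population
#'   `sizes_start` (after burn-in) and `sizes` (final).
#' @export
simulate_homeostasis <- function(config, burnin = 2, record_counts = FALSE) {
  basin <- lattice_basin(config$params)
  pops <- vector("list", config$n_populations)
  logs <- vector("list", config$n_populations)
  sizes_start <- integer(config$n_populations)
  for (i in seq_len(config$n_populations)) {
    set.seed(derive_seed(config$seed, "init", i))
    p <- init_population(config, basin)
    set.seed(derive_seed(config$seed, "dynamics", i))
    if (burnin > 0) {
      p <- run_population(p, until = "time", t = burnin * p$T,
                          record_counts = FALSE)
      p$log <- NULL
    }
    sizes_start[i] <- nrow(p$states)
    p <- run_population(p, until = "time", t = config$duration,
                        record_counts = record_counts)
    pops[[i]] <- p
    logs[[i]] <- p$log
  }
  list(populations = pops, logs = logs, scb = scb_rate(logs),
       sizes_start = sizes_start,
       sizes = vapply(pops, function(p) nrow(p$states), integer(1)))
}
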