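# Mutation-accumulation protocol: per-cell parameter mutations, the
# multi-phase experiment, and its survival / SCB / swarm / size metrics.

#' Mutation model configuration
#'
#' Mutations perturb one randomly chosen alpha rate constant of a cell's
#' switch by `epsilon`, where `|epsilon|` is exponential with mean `lambda`
#' and the sign is negative with probability `p` (most mutations weaken an
#' interaction). The mutated rate is floored at zero; `beta`, `gamma`, `n`
#' and the topology are never mutated.
#'
#' @param p probability of a negative-value mutation (typical values 0.85,
#'   0.90, 0.95, 0.99).
#' @param lambda mean of the exponential magnitude distribution (typical
#'   values 2, 5, 10).
#' @param phases total protocol phases including the unmutated phase 0
#'   (default 11: phase 0 plus 10 mutation phases).
#' @param seed optional seed overriding the population config's seed in
#'   [run_phases()].
#' @return An object of class `mutation_config`.
#' @export
mutation_config <- function(p = 0.85, lambda = 5, phases = 11L, seed = NULL) {
  if (p < 0 || p > 1) stop("'p' must lie in [0, 1]")
  if (lambda <= 0) stop("'lambda' must be positive")
  phases <- as.integer(phases)
  if (phases < 1L) stop("'phases' must be >= 1")
  structure(list(p = p, lambda = lambda, phases = phases,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "mutation_config")
}

# vectorized signed mutation sizes: e ~ Exp(mean lambda), sign negative with
# probability p (r ~ U(0,1), negative iff r <= p)
rmutation <- function(k, p, lambda) {
  e <- rexp(k, rate = 1 / lambda)
  r <- runif(k)
  ifelse(r <= p, -e, e)
}

#' Mutate one switch parameter of a cell
#'
#' Picks one of the cell's `4 m` alpha rate constants uniformly at random and
#' adds a signed exponential perturbation (see [mutation_config()]); the
#' result is floored at zero. All other parameters are untouched.
#'
#' @param params the cell's current [switch_params()].
#' @param config a [mutation_config()].
#' @return The mutated `switch_params`.
#' @export
mutate_params <- function(params, config) {
  m <- params$m
  idx <- sample.int(4L * m, 1L)
  eps <- rmutation(1L, config$p, config$lambda)
  al <- alpha_vector(params)
  al[idx] <- max(al[idx] + eps, 0)
  alphas_to_params(al, params)
}

# apply one mutation to every cell of a population and recompute each cell's
# attractors by Newton continuation from its previous attractor locations
mutate_population <- function(pop, config, fallback_sums) {
  n <- nrow(pop$states)
  if (n == 0L) return(pop)
  m <- pop$params$m
  idx <- sample.int(4L * m, n, replace = TRUE)
  eps <- rmutation(n, config$p, config$lambda)
  sel <- cbind(seq_len(n), idx)
  pop$alphas[sel] <- pmax(pop$alphas[sel] + eps, 0)
  pop$attr <- cpp_attractors_update(pop$alphas, pop$params$beta, pop$params$n,
                                    pop$params$gamma, m, pop$attr,
                                    fallback_sums)
  pop
}

#' Run the multi-phase mutation-accumulation protocol
#'
#' Phase 0 runs unmutated populations until every lineage has completed at
#' least `k` divisions (time-capped at `4 T`). At the start of every later
#' phase each cell of every surviving population receives exactly one
#' parameter mutation (independent draws per cell), its attractors are
#' recomputed from its own mutated switch, and the phase runs under the same
#' division rule. Daughters inherit their mother's mutated parameters. A
#' population survives a phase if at least one stem cell remains; extinct
#' populations never revive.
#'
#' @param pop_config a [population_config()].
#' @param mut_config a [mutation_config()].
#' @param k divisions per lineage required to end a phase (default 2).
#' @param keep_logs keep full division logs per phase (memory-heavy).
#' @return An object of class `mutation_protocol`: a list of per-phase
#'   snapshots plus the configurations. Each snapshot records the phase
#'   index, surviving-population count, pooled SCB rate over the phase's
#'   divisions, per-population sizes (0 = extinct), the surviving cells'
#'   within-phase and cumulative stem-daughter fractions, their middle
#'   attractor master-pair locations, and the phase duration.
#' @examples \donttest{
#' res <- run_phases(population_config(n_populations = 20,
#'                                     cells_per_population = 50, seed = 7),
#'                   mutation_config(p = 0.85, lambda = 5, phases = 3))
#' survivors(res)
#' }
#' @export
run_phases <- function(pop_config, mut_config, k = 2L, keep_logs = FALSE) {
  seed <- mut_config$seed %||% pop_config$seed
  params <- pop_config$params
  basin <- lattice_basin(params)
  fallback <- do.call(rbind, lapply(basin$attractors[c("A", "B", "C")],
                                    function(a) a$location))
  npop <- pop_config$n_populations
  pops <- vector("list", npop)
  for (i in seq_len(npop)) {
    set.seed(derive_seed(seed, "init", i))
    pops[[i]] <- init_population(pop_config, basin)
  }
  alive <- rep(TRUE, npop)
  snapshots <- vector("list", mut_config$phases)
  for (ph in seq_len(mut_config$phases) - 1L) {
    if (ph > 0L) {
      set.seed(derive_seed(seed, "mutation", ph))
      for (i in which(alive))
        pops[[i]] <- mutate_population(pops[[i]], mut_config, fallback)
    }
    phase_logs <- vector("list", npop)
    t_started <- vapply(pops, function(p) p$time, numeric(1))
    for (i in which(alive)) {
      pops[[i]]$counters[, c("ph_divisions", "ph_stem", "ph_total")] <- 0
      pops[[i]]$log <- NULL
      set.seed(derive_seed(seed, "dynamics", ph, i))
      pops[[i]] <- run_population(pops[[i]], until = "divisions", k = k,
                                  record_counts = FALSE)
      phase_logs[[i]] <- pops[[i]]$log
    }
    sizes <- vapply(seq_len(npop), function(i)
      if (alive[i]) nrow(pops[[i]]$states) else 0L, integer(1))
    surv_cells <- lapply(which(alive & sizes > 0), function(i) pops[[i]])
    cnt <- do.call(rbind, lapply(surv_cells, function(p) p$counters))
    att <- do.call(rbind, lapply(surv_cells, function(p) p$attr))
    frac_phase <- frac_cum <- numeric(0)
    attC <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x1", "y1")))
    if (!is.null(cnt) && nrow(cnt) > 0) {
      has_div <- cnt[, "ph_total"] > 0
      frac_phase <- cnt[has_div, "ph_stem"] / cnt[has_div, "ph_total"]
      has_cum <- cnt[, "total_daughters"] > 0
      frac_cum <- cnt[has_cum, "stem_daughters"] / cnt[has_cum, "total_daughters"]
      hasC <- att[, 21] > 0.5
      attC <- cbind(x1 = att[hasC, 15], y1 = att[hasC, 18])
    }
    nd <- sum(vapply(phase_logs, function(l) if (is.null(l)) 0L else nrow(l),
                     integer(1)))
    snapshots[[ph + 1L]] <- list(
      phase = ph,
      survivors = sum(sizes > 0),
      scb = if (nd > 0) scb_rate(phase_logs) else NA_real_,
      n_divisions = nd,
      sizes = sizes,
      stem_fractions = unname(sort(frac_phase, decreasing = TRUE)),
      stem_fractions_cumulative = unname(sort(frac_cum, decreasing = TRUE)),
      middle_attractors = attC,
      duration = max(c(0, vapply(which(alive), function(i)
        pops[[i]]$time - t_started[i], numeric(1)))),
      logs = if (keep_logs) phase_logs else NULL)
    alive <- alive & sizes > 0
    if (!any(alive)) {
      for (ph2 in seq(ph + 1L, mut_config$phases - 1L)) {
        if (ph2 > mut_config$phases - 1L) break
        snapshots[[ph2 + 1L]] <- list(phase = ph2, survivors = 0L,
                                      scb = NA_real_, n_divisions = 0L,
                                      sizes = rep(0L, npop),
                                      stem_fractions = numeric(0),
                                      stem_fractions_cumulative = numeric(0),
                                      middle_attractors = attC[0, , drop = FALSE],
                                      duration = 0, logs = NULL)
      }
      break
    }
  }
  structure(list(snapshots = Filter(Negate(is.null), snapshots),
                 pop_config = pop_config, mut_config = mut_config,
                 seed = seed),
            class = "mutation_protocol")
}

#' @export
print.mutation_protocol <- function(x, ...) {
  cat(sprintf("mutation_protocol: %d phase(s), p = %g, lambda = %g, %d population(s)\n",
              length(x$snapshots), x$mut_config$p, x$mut_config$lambda,
              x$pop_config$n_populations))
  df <- data.frame(phase = survivors(x)$phase,
                   survivors = survivors(x)$survivors,
                   scb = round(scb_trajectory(x)$scb, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Per-phase surviving-population counts
#' @param protocol a `mutation_protocol`.
#' @return Data frame with `phase` and `survivors`.
#' @export
survivors <- function(protocol) {
  data.frame(phase = vapply(protocol$snapshots, `[[`, integer(1), "phase"),
             survivors = vapply(protocol$snapshots, function(s)
               as.integer(s$survivors), integer(1)))
}

#' Per-phase pooled stem-cell birth rates
#' @param protocol a `mutation_protocol`.
#' @return Data frame with `phase` and `scb`.
#' @export
scb_trajectory <- function(protocol) {
  data.frame(phase = vapply(protocol$snapshots, `[[`, integer(1), "phase"),
             scb = vapply(protocol$snapshots, function(s)
               as.numeric(s$scb), numeric(1)))
}

#' Top-k per-cell stem-birth fractions per phase
#'
#' For each phase, the `k` highest per-cell stem-daughter fractions pooled
#' over all surviving populations (the swarm-plot statistic; cells without a
#' division in the phase are excluded). When fewer than `k` cells qualify all
#' are returned and the row is flagged `short`.
#'
#' @param snapshots a `mutation_protocol` or its `$snapshots` list.
#' @param k number of cells per phase (default 50).
#' @param cumulative use lifetime (since phase 0) fractions instead of
#'   within-phase fractions.
#' @return Data frame with `phase`, `rank`, `fraction`, `short`.
#' @export
swarm_top_k <- function(snapshots, k = 50L, cumulative = FALSE) {
  if (inherits(snapshots, "mutation_protocol")) snapshots <- snapshots$snapshots
  field <- if (cumulative) "stem_fractions_cumulative" else "stem_fractions"
  out <- lapply(snapshots, function(s) {
    fr <- s[[field]]
    if (length(fr) == 0L)
      return(data.frame(phase = integer(0), rank = integer(0),
                        fraction = numeric(0), short = logical(0)))
    top <- sort(fr, decreasing = TRUE)[seq_len(min(k, length(fr)))]
    data.frame(phase = s$phase, rank = seq_along(top), fraction = top,
               short = length(fr) < k)
  })
  do.call(rbind, out)
}

#' Determinant noise relative to the unmutated middle attractor
#'
#' Noise is the absolute difference between a cell's determinant counts and
#' the expected counts at the (unmutated) middle attractor, per determinant.
#'
#' @param state determinant counts: a vector, or a matrix with one row per
#'   cell.
#' @param reference the unmutated middle attractor location (same length as
#'   a state).
#' @return Componentwise `|state - reference|`, same shape as `state`.
#' @examples
#' noise_metric(c(96, 88), c(92, 92))  # 4 4
#' @export
noise_metric <- function(state, reference) {
  if (is.matrix(state)) {
    if (ncol(state) != length(reference))
      stop("reference length must match state dimension")
    return(abs(sweep(state, 2, reference)))
  }
  if (length(state) != length(reference))
    stop("reference length must match state dimension")
  abs(state - reference)
}

#' Population-size histogram per phase
#'
#' Counts populations per size, per phase, including extinct populations in
#' the size-0 bin; totals equal the number of replicate populations in every
#' phase.
#'
#' @param snapshots a `mutation_protocol` or its `$snapshots` list.
#' @return Data frame with `phase`, `size`, `count`.
#' @export
size_distribution <- function(snapshots) {
  if (inherits(snapshots, "mutation_protocol")) snapshots <- snapshots$snapshots
  out <- lapply(snapshots, function(s) {
    tb <- table(s$sizes)
    data.frame(phase = s$phase, size = as.integer(names(tb)),
               count = as.integer(tb))
  })
  do.call(rbind, out)
}
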