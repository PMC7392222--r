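# Configuration loading, deterministic seed derivation, and tabular/JSON
# output writers with a reproducibility manifest.

#' Derive a named sub-stream seed from a master seed
#'
#' Deterministically maps a master seed plus any number of labels (strings or
#' integers, e.g. `"dynamics", phase, population`) to a positive 32-bit seed,
#' so every module draws from its own named stream of the single run seed.
#'
#' @param seed master seed (integer).
#' @param ... labels identifying the sub-stream.
#' @return A positive integer seed below 2^31.
#' @examples
#' derive_seed(1, "init", 3)
#' @export
derive_seed <- function(seed, ...) {
  s <- as.double(as.integer(seed) %% 2147483647)
  for (ch in utf8ToInt(paste(c(...), collapse = "/")))
    s <- (s * 31 + ch) %% 2147483647
  as.integer(s) + 1L
}

config_keys <- c("preset", "switch", "populations", "cells", "seed",
                 "duration", "population_cap", "p", "lambda", "phases")
switch_keys <- c("alpha_A", "alpha_I", "alpha_A_y", "alpha_I_y",
                 "beta", "gamma", "n", "m")

#' Load and validate a run configuration
#'
#' Reads a JSON configuration, fills defaults (the two-element homeostasis
#' preset, 1000 populations of 50 cells), and enforces all parameter
#' invariants. Unknown keys are rejected by name. An explicit `switch`
#' object overrides the `preset`.
#'
#' @param path path to a JSON file.
#' @return A list with the validated `params` ([switch_params()]), `pop`
#'   ([population_config()]), `mut` ([mutation_config()]) and the `raw`
#'   parsed JSON.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  params <- if (!is.null(raw[["switch"]])) {
    sw <- raw[["switch"]]
    bad <- setdiff(names(sw), switch_keys)
    if (length(bad))
      stop("unknown switch key(s): ", paste(bad, collapse = ", "))
    need <- c("alpha_A", "alpha_I", "beta", "gamma", "n")
    miss <- setdiff(need, names(sw))
    if (length(miss))
      stop("missing switch key(s): ", paste(miss, collapse = ", "))
    switch_params(alpha_A = sw[["alpha_A"]], alpha_I = sw[["alpha_I"]],
                  beta = sw[["beta"]], gamma = sw[["gamma"]], n = sw[["n"]],
                  m = sw[["m"]] %||% 1L,
                  alpha_A_y = sw[["alpha_A_y"]] %||% sw[["alpha_A"]],
                  alpha_I_y = sw[["alpha_I_y"]] %||% sw[["alpha_I"]])
  } else {
    switch_preset(raw[["preset"]] %||% "two-element")
  }
  pop <- population_config(
    n_populations = raw[["populations"]] %||% 1000L,
    cells_per_population = raw[["cells"]] %||% 50L,
    seed = raw[["seed"]] %||% 1L,
    duration = raw[["duration"]],
    population_cap = raw[["population_cap"]] %||% 1000L,
    params = params)
  mut <- mutation_config(p = raw[["p"]] %||% 0.85,
                         lambda = raw[["lambda"]] %||% 5,
                         phases = raw[["phases"]] %||% 11L)
  list(params = params, pop = pop, mut = mut, raw = raw)
}

#' Serialize switch parameters to a JSON-compatible list
#' @param params a [switch_params()].
#' @return A named list with keys `alpha_A`, `alpha_I`, `alpha_A_y`,
#'   `alpha_I_y`, `beta`, `gamma`, `n`, `m`.
#' @export
switch_to_config <- function(params) {
  list(alpha_A = params$alpha_A, alpha_I = params$alpha_I,
       alpha_A_y = params$alpha_A_y, alpha_I_y = params$alpha_I_y,
       beta = params$beta, gamma = params$gamma,
       n = params$n, m = params$m)
}

#' Write analysis results with a run manifest
#'
#' Writes the CSV/JSON outputs appropriate to the result type and, last, a
#' `manifest.json` recording the tool version, the resolved configuration and
#' seed, timestamps, and an MD5 checksum per written file. Supported result
#' types: `mutation_protocol` (survival.csv, scb.csv, swarm.csv, sizes.csv),
#' `switch_fixed_points` (fixed_points.csv/.json), parameter-sweep data
#' frames (sweep.csv), and [simulate_homeostasis()] results (divisions.csv,
#' summary.json).
#'
#' @param results a supported result object.
#' @param out_dir output directory (created if needed).
#' @param config optional configuration list echoed into the manifest.
#' @param seed optional seed echoed into the manifest.
#' @return Invisibly, the manifest list.
#' @export
write_outputs <- function(results, out_dir, config = NULL, seed = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  }
  files <- character(0)
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  if (inherits(results, "mutation_protocol")) {
    preset <- results$pop_config$preset %||% "custom"
    p <- results$mut_config$p
    lam <- results$mut_config$lambda
    sv <- survivors(results)
    wr(cbind(sv[1], preset = preset, p = p, lambda = lam, sv[-1]),
       "survival.csv")
    sc <- scb_trajectory(results)
    wr(cbind(sc[1], preset = preset, p = p, lambda = lam, sc[-1]), "scb.csv")
    wr(swarm_top_k(results), "swarm.csv")
    wr(size_distribution(results), "sizes.csv")
    config <- config %||% list(
      populations = results$pop_config$n_populations,
      cells = results$pop_config$cells_per_population,
      preset = preset, p = p, lambda = lam,
      phases = results$mut_config$phases,
      switch = switch_to_config(results$pop_config$params))
    seed <- seed %||% results$seed
  } else if (inherits(results, "switch_fixed_points")) {
    wr(as.data.frame(results), "fixed_points.csv")
    js <- lapply(seq_len(nrow(results)), function(i) list(
      location = as.numeric(results[i, seq_len(ncol(results) - 4L)]),
      Sx = results$Sx[i], Sy = results$Sy[i],
      stability = results$stability[i],
      eigenvalues_re = Re(attr(results, "eigenvalues")[[i]]),
      eigenvalues_im = Im(attr(results, "eigenvalues")[[i]])))
    path <- file.path(out_dir, "fixed_points.json")
    jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA)
    files <- c(files, path)
    config <- config %||% list(switch = switch_to_config(attr(results, "params")))
  } else if (is.data.frame(results) && all(c("param", "value") %in% names(results))) {
    wr(results, "sweep.csv")
  } else if (is.list(results) && !is.null(results$logs)) {
    logs <- Filter(Negate(is.null), results$logs)
    if (length(logs)) {
      df <- do.call(rbind, lapply(seq_along(logs), function(i)
        cbind(population = i, logs[[i]])))
      wr(df, "divisions.csv")
    }
    path <- file.path(out_dir, "summary.json")
    jsonlite::write_json(list(scb = results$scb, sizes = results$sizes),
                         path, auto_unbox = TRUE, digits = NA)
    files <- c(files, path)
  } else {
    stop("unsupported results object of class ",
         paste(class(results), collapse = "/"))
  }
  manifest <- list(
    tool = "tristem",
    version = as.character(packageVersion("tristem")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
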