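# Configuration files, seed management, tidy writers and run manifests.

config_keys <- c("p_c", "p_n", "n_guides", "p_nf", "placement", "p_y",
                 "xo_fertility", "p_x_xo", "k", "litter_mean", "r_max",
                 "f_max", "cycles_per_year", "strategy", "p_x", "p_y_yo",
                 "inoculum_size", "years", "replicates", "seed")

#' Load a simulation configuration file
#'
#' Reads a flat key-value document (JSON, or YAML-style `key: value` lines;
#' `#` comments and blank lines are ignored) whose keys are the parameter
#' symbols used throughout the model (`p_c`, `p_n`, `n_guides`, `p_nf`,
#' `p_y`, `xo_fertility`, `p_x_xo`, `f_max`, `litter_mean`, `r_max`, `k`,
#' plus `placement`, `strategy`, `p_x`, `p_y_yo`, `inoculum_size`, `years`,
#' `replicates`, `seed`, `cycles_per_year`). Absent keys take the baseline
#' defaults; unknown keys and out-of-range values are errors.
#'
#' @param path Path to the config file.
#' @return A validated [sim_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  txt <- readLines(path, warn = FALSE)
  body <- trimws(paste(txt, collapse = "\n"))
  vals <- if (nzchar(body) && startsWith(body, "{")) {
    jsonlite::fromJSON(body, simplifyVector = TRUE)
  } else {
    parse_flat_yaml(txt)
  }
  config_from_list(vals)
}

parse_flat_yaml <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L)
      stop("malformed config line: ", ln, call. = FALSE)
    key <- m[2]
    val <- trimws(gsub('^"|"$', "", m[3]))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Build a configuration from a flat named list
#'
#' @param vals Named list of parameter values (see [load_config()]).
#' @return A [sim_config()].
#' @export
config_from_list <- function(vals) {
  unknown <- setdiff(names(vals), config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  g <- function(key, default) vals[[key]] %||% default
  drive <- drive_params(
    p_c = g("p_c", 0.95), p_n = g("p_n", 0),
    n_guides = g("n_guides", 3), p_nf = g("p_nf", 1),
    placement = g("placement", "noncoding"), p_y = g("p_y", 1),
    xo_fertility = g("xo_fertility", 0.6), p_x_xo = g("p_x_xo", 0.66))
  demog <- demog_params(
    k = g("k", 10000), litter_mean = g("litter_mean", 6),
    r_max = g("r_max", 7.76), f_max = g("f_max", 1),
    cycles_per_year = g("cycles_per_year", 10))
  strategy <- g("strategy", "ychope")
  xs <- if (strategy == "xshredder" || !is.null(vals$p_x) ||
            !is.null(vals$p_y_yo))
    xshredder_params(p_x = g("p_x", 1), p_y_yo = g("p_y_yo", 1))
  else NULL
  sim_config(drive = drive, demog = demog, strategy = strategy,
             xshredder = xs, inoculum_size = g("inoculum_size", 100),
             years = g("years", 10), replicates = g("replicates", 1000),
             seed = g("seed", 1))
}

#' Spawn deterministic child seeds
#'
#' Derives `n` distinct child seeds from a root seed (a deterministic draw
#' without replacement from 1..2^31-2, seeded by the root). Used to give
#' every replicate its own reproducible stream. The caller's RNG state is
#' restored afterwards.
#'
#' @param root_seed Root seed (non-negative integer).
#' @param n Number of child seeds.
#' @return An integer vector of `n` distinct seeds.
#' @export
spawn_seeds <- function(root_seed, n) {
  stopifnot(n >= 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(root_seed)
  sample.int(2147483646L, n)
}

#' Write tidy per-cycle trajectories
#'
#' Writes one row per replicate per cycle with columns `replicate`, `year`,
#' `cycle`, `N`, `XX`, `XY`, `XO`, `WW`, `WG`, `GG`, `WR`, `GR`, `RR`,
#' `eradicated`.
#'
#' @param results A `replicate_summary` (with kept results) or a list of
#'   `sim_result` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(results, path) {
  if (inherits(results, "replicate_summary")) {
    if (is.null(results$results))
      stop("replicate_summary was built with keep_results = FALSE",
           call. = FALSE)
    results <- results$results
  }
  if (inherits(results, "sim_result")) results <- list(results)
  rows <- lapply(seq_along(results), function(r) {
    res <- results[[r]]
    tr <- res$trajectory
    data.frame(replicate = r, year = tr$year, cycle = tr$cycle,
               tr[, c("N", "XX", "XY", "XO",
                      "WW", "WG", "GG", "WR", "GR", "RR")],
               eradicated = res$eradicated)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Build a run manifest
#'
#' A manifest records everything needed to reproduce a replicate batch
#' bitwise: the full parameter echo, the root seed and derived per-replicate
#' seeds, the package version and wall-clock metadata.
#'
#' @param config A [sim_config()].
#' @param replicates Number of replicates the manifest covers.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(config, replicates = config$replicates) {
  structure(list(
    parameters = list(
      drive = unclass(config$drive),
      demog = unclass(config$demog),
      xshredder = if (!is.null(config$xshredder))
        unclass(config$xshredder) else NULL,
      strategy = config$strategy,
      inoculum_size = config$inoculum_size,
      years = config$years
    ),
    root_seed = config$seed,
    replicate_seeds = spawn_seeds(config$seed, replicates),
    package_version = as.character(packageVersion("ychope")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
  ), class = "run_manifest")
}

#' Write a run manifest as JSON
#'
#' @param manifest A [run_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Re-run a replicate batch from a manifest
#'
#' Reconstructs the configuration and per-replicate seeds recorded in a
#' manifest (or a JSON file written by [write_manifest()]) and reruns the
#' batch; given the same package version the outputs are bitwise identical
#' to the original run.
#'
#' @param manifest A `run_manifest` or the path to a manifest JSON file.
#' @return A `replicate_summary`.
#' @export
replay_manifest <- function(manifest) {
  if (is.character(manifest))
    manifest <- jsonlite::fromJSON(manifest, simplifyVector = TRUE)
  p <- manifest$parameters
  drive <- do.call(drive_params, p$drive)
  demog <- do.call(demog_params, p$demog)
  xs <- if (!is.null(p$xshredder)) do.call(xshredder_params, p$xshredder)
  cfg <- sim_config(drive = drive, demog = demog, strategy = p$strategy,
                    xshredder = xs, inoculum_size = p$inoculum_size,
                    years = p$years,
                    replicates = length(manifest$replicate_seeds),
                    seed = manifest$root_seed)
  run_replicates(cfg)
}
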