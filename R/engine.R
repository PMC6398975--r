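# Experiment drivers: population initialization, the five-stage breeding
# cycle, single runs, replicate batches and eradication-threshold searches.

trajectory_cols <- c("N", "XX", "XY", "XO",
                     "WW", "WG", "GG", "WR", "GR", "RR", "carriers")

#' Initialize a population
#'
#' Builds K wildtype individuals (K/2 XX females, K/2 XY males, all alleles
#' wildtype with the full complement of susceptible sites) plus the
#' inoculum: drive-heterozygous XX females for the `"ychope"` strategy, or
#' XY males carrying the Y-linked X-shredding cassette for `"xshredder"`.
#'
#' @param config A [sim_config()].
#' @return A list of [individual()]s.
#' @export
initialize_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$demog$k
  if (k %% 2L != 0L) stop("`k` must be even", call. = FALSE)
  s <- config$drive$n_guides
  wt <- allele("wildtype", s)
  base <- c(
    replicate(k / 2L, individual("XX", wt, wt), simplify = FALSE),
    replicate(k / 2L, individual("XY", wt, wt), simplify = FALSE)
  )
  ino <- if (config$inoculum_size > 0L) {
    if (config$strategy == "ychope")
      replicate(config$inoculum_size,
                individual("XX", allele("drive"), wt), simplify = FALSE)
    else
      replicate(config$inoculum_size,
                individual("XY", wt, wt, y_drive = TRUE), simplify = FALSE)
  } else list()
  c(base, ino)
}

# integer-array layout of the same initial population, for the engine
init_arrays <- function(config) {
  k <- config$demog$k
  if (k %% 2L != 0L) stop("`k` must be even", call. = FALSE)
  wt <- 1L + 2L * config$drive$n_guides
  ni <- config$inoculum_size
  if (config$strategy == "ychope") {
    allosome <- c(rep(0L, k / 2L), rep(1L, k / 2L), rep(0L, ni))
    am <- c(rep(wt, k), rep(0L, ni))
    ap <- rep(wt, k + ni)
    yd <- rep(0L, k + ni)
  } else {
    allosome <- c(rep(0L, k / 2L), rep(1L, k / 2L), rep(1L, ni))
    am <- rep(wt, k + ni)
    ap <- rep(wt, k + ni)
    yd <- c(rep(0L, k), rep(1L, ni))
  }
  list(allosome = allosome, allele_m = am, allele_p = ap,
       age = rep(1L, k + ni), y_drive = yd)
}

pop_to_arrays <- function(population) {
  amap <- c(XX = 0L, XY = 1L, XO = 2L)
  list(
    allosome = vapply(population, function(i) amap[[i$allosomes]], 0L),
    allele_m = vapply(population, function(i) allele_code(i$allele_m), 0L),
    allele_p = vapply(population, function(i) allele_code(i$allele_p), 0L),
    age = vapply(population, function(i) i$age, 0L),
    y_drive = vapply(population, function(i) as.integer(i$y_drive), 0L)
  )
}

engine_pars <- function(config, n_cycles) {
  ab <- calibrate_survival(config$demog, clamp = TRUE)
  xs <- config$xshredder %||% xshredder_params(0, 1)
  list(
    n_cycles = as.integer(n_cycles),
    p_y = config$drive$p_y,
    p_x_xo = config$drive$p_x_xo,
    xo_fertility = config$drive$xo_fertility,
    litter_mean = config$demog$litter_mean,
    f_max = config$demog$f_max,
    surv_a = unname(ab["a"]),
    surv_b = unname(ab["b"]),
    strategy = if (config$strategy == "ychope") 0L else 1L,
    p_x = xs$p_x,
    p_y_yo = xs$p_y_yo,
    per_gamete = xs$per_gamete
  )
}

#' Run one simulation
#'
#' Runs `years * cycles_per_year` breeding cycles (or until the population
#' reaches zero). The state is censused after mortality and aging each cycle
#' (pre-breeding census convention); cycle 0 is the initial, post-inoculation
#' state. Fully reproducible for a given `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Seed for this run (defaults to `config$seed`).
#' @param engine `"cpp"` (compiled, default) or `"r"` (pure-R reference
#'   implementation built from the unit-level operations; ychope strategy
#'   only, intended for cross-validation at small K).
#' @return An object of class `sim_result`: a list with `trajectory` (a data
#'   frame with columns `cycle`, `year`, `N`, `XX`, `XY`, `XO`, `WW`, `WG`,
#'   `GG`, `WR`, `GR`, `RR`, `carriers`), `eradicated`, `eradication_cycle`
#'   (`NA` if not eradicated), `seed` and `config`.
#' @examples
#' cfg <- sim_config(demog = demog_params(k = 200), inoculum_size = 4,
#'                   years = 2, replicates = 1)
#' run_simulation(cfg, seed = 42)
#' @export
run_simulation <- function(config, seed = config$seed,
                           engine = c("cpp", "r")) {
  stopifnot(inherits(config, "sim_config"))
  engine <- match.arg(engine)
  n_cycles <- config$years * config$demog$cycles_per_year
  set.seed(seed)
  tables <- make_transition_tables(config$drive)
  if (engine == "cpp") {
    res <- cpp_run_simulation(init_arrays(config), tables,
                              engine_pars(config, n_cycles))
    traj <- res$traj
    erad_cycle <- res$eradication_cycle
  } else {
    if (config$strategy != "ychope")
      stop('engine = "r" supports the "ychope" strategy only', call. = FALSE)
    out <- r_engine_run(config, tables, n_cycles)
    traj <- out$traj
    erad_cycle <- out$eradication_cycle
  }
  colnames(traj) <- trajectory_cols
  df <- data.frame(cycle = 0:n_cycles,
                   year = (0:n_cycles) / config$demog$cycles_per_year)
  df <- cbind(df, as.data.frame(traj))
  structure(list(
    trajectory = df,
    eradicated = erad_cycle >= 0L,
    eradication_cycle = if (erad_cycle >= 0L) erad_cycle else NA_integer_,
    seed = seed,
    config = config
  ), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf("<sim_result> %d cycles, final N = %d, %s\n",
              nrow(tr) - 1L, tr$N[nrow(tr)],
              if (x$eradicated)
                sprintf("eradicated at cycle %d", x$eradication_cycle)
              else "not eradicated"))
  invisible(x)
}

#' Advance a population by one breeding cycle (reference implementation)
#'
#' Pure-R implementation of the five-stage cycle built directly from
#' [allocate_mates()], [make_litter()] and [apply_mortality_and_age()].
#' Used for unit tests and cross-validation of the compiled engine; the
#' ychope strategy only.
#'
#' @param population List of [individual()]s.
#' @param config A [sim_config()].
#' @param tables Optional precomputed homing tables.
#' @return The population after one full cycle.
#' @export
step_cycle <- function(population, config, tables = NULL) {
  if (length(population) == 0L) return(population)
  if (is.null(tables)) tables <- make_transition_tables(config$drive)
  n_census <- length(population)
  sex <- vapply(population, function(i) i$sex, "")
  pairs <- allocate_mates(which(sex == "female"), which(sex == "male"),
                          config$demog$f_max)
  newborns <- list()
  for (i in seq_len(nrow(pairs)))
    newborns <- c(newborns,
                  make_litter(population[[pairs$female[i]]],
                              population[[pairs$male[i]]],
                              config$drive, config$demog, tables))
  apply_mortality_and_age(c(population, newborns), n_census, config$demog)
}

r_engine_run <- function(config, tables, n_cycles) {
  pop <- initialize_population(config)
  traj <- matrix(0L, n_cycles + 1L, length(trajectory_cols))
  traj[1L, ] <- census_counts(pop)
  erad <- -1L
  for (t in seq_len(n_cycles)) {
    if (length(pop) == 0L) break
    pop <- step_cycle(pop, config, tables)
    traj[t + 1L, ] <- census_counts(pop)
    if (length(pop) == 0L && erad < 0L) erad <- t
  }
  list(traj = traj, eradication_cycle = erad)
}

census_counts <- function(population) {
  out <- setNames(integer(length(trajectory_cols)), trajectory_cols)
  if (length(population) == 0L) return(unname(out))
  allos <- vapply(population, function(i) i$allosomes, "")
  c1 <- vapply(population, function(i) allele_code(i$allele_m), 0L)
  c2 <- vapply(population, function(i) allele_code(i$allele_p), 0L)
  g <- genotype_label(c1, c2)
  out["N"] <- length(population)
  for (a in c("XX", "XY", "XO")) out[a] <- sum(allos == a)
  for (gg in c("WW", "WG", "GG", "WR", "GR", "RR")) out[gg] <- sum(g == gg)
  out["carriers"] <- sum(c1 == 0L | c2 == 0L |
                           vapply(population, function(i) i$y_drive, FALSE))
  unname(out)
}

#' Run replicate simulations
#'
#' Runs `replicates` independent simulations with per-replicate seeds
#' derived from the root seed by [spawn_seeds()], and summarizes them:
#' eradication probability (the fraction of replicates reaching N = 0
#' within the horizon), per-cycle means and percentile-based 95% intervals
#' of every trajectory series, and the final-population-size summary.
#'
#' @param config A [sim_config()].
#' @param replicates Number of replicates (defaults to `config$replicates`).
#' @param keep_results Keep the individual `sim_result` objects (default
#'   `TRUE`; set `FALSE` to save memory in large batches).
#' @return An object of class `replicate_summary`.
#' @export
run_replicates <- function(config, replicates = config$replicates,
                           keep_results = TRUE) {
  stopifnot(replicates >= 1)
  seeds <- spawn_seeds(config$seed, replicates)
  results <- vector("list", replicates)
  n_cycles <- config$years * config$demog$cycles_per_year
  series <- array(0, dim = c(replicates, n_cycles + 1L,
                             length(trajectory_cols)),
                  dimnames = list(NULL, NULL, trajectory_cols))
  erad <- logical(replicates)
  erad_cycle <- rep(NA_integer_, replicates)
  for (r in seq_len(replicates)) {
    res <- run_simulation(config, seed = seeds[r])
    series[r, , ] <- as.matrix(res$trajectory[, trajectory_cols])
    erad[r] <- res$eradicated
    erad_cycle[r] <- res$eradication_cycle
    if (keep_results) results[[r]] <- res
  }
  ci <- function(m) apply(m, 2, quantile, probs = c(0.025, 0.975),
                          names = FALSE)
  summaries <- lapply(setNames(nm = trajectory_cols), function(cn) {
    m <- series[, , cn, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
    b <- ci(m)
    data.frame(cycle = 0:n_cycles, mean = colMeans(m),
               lo = b[1, ], hi = b[2, ])
  })
  final_n <- series[, n_cycles + 1L, "N"]
  structure(list(
    eradication_probability = mean(erad),
    eradicated = erad,
    eradication_cycle = erad_cycle,
    trajectory_summary = summaries,
    final_n = data.frame(mean = mean(final_n),
                         lo = unname(quantile(final_n, 0.025)),
                         hi = unname(quantile(final_n, 0.975))),
    replicates = replicates,
    seeds = seeds,
    results = if (keep_results) results else NULL,
    config = config
  ), class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf(
    "<replicate_summary> %d replicates: eradication probability %.3f, final N %.1f [%.1f, %.1f]\n",
    x$replicates, x$eradication_probability,
    x$final_n$mean, x$final_n$lo, x$final_n$hi))
  invisible(x)
}

# eradication fraction with early bail-out once the required fraction is
# unreachable (used by threshold searches; required_fraction = 1 bails on
# the first surviving replicate)
erad_fraction <- function(config, replicates, max_failures = replicates,
                          root_seed = config$seed) {
  seeds <- spawn_seeds(root_seed, replicates)
  nerad <- 0L; nfail <- 0L; nrun <- 0L
  for (r in seq_len(replicates)) {
    res <- run_simulation(config, seed = seeds[r])
    nrun <- nrun + 1L
    if (res$eradicated) nerad <- nerad + 1L else nfail <- nfail + 1L
    if (nfail > max_failures) break
  }
  list(fraction = nerad / replicates, eradicated = nerad, run = nrun,
       qualified = nfail <= max_failures)
}

#' Find the minimum Y-shredding efficiency for eradication
#'
#' Scans a sorted grid of Y-shredding efficiencies (`p_y`) from the bottom
#' and returns the smallest value whose replicate eradication fraction is at
#' least `required_fraction`. Grid points are abandoned as soon as enough
#' replicates have failed to eradicate for the point to be disqualified.
#'
#' @param config A [sim_config()]; `config$drive$p_y` is overridden by the
#'   grid values.
#' @param py_grid Ascending vector of candidate efficiencies.
#' @param required_fraction Required eradication fraction in (0, 1]; 1 means
#'   every replicate must eradicate ("guaranteed" eradication at finite
#'   replicates).
#' @param replicates Replicates per grid point.
#' @return A list of class `threshold_result` with `threshold` (`NA` if no
#'   grid point qualifies) and `details`, one row per evaluated grid point.
#' @export
find_eradication_threshold <- function(config, py_grid,
                                       required_fraction = 1,
                                       replicates = 30) {
  if (length(py_grid) == 0L) stop("`py_grid` must be non-empty", call. = FALSE)
  if (is.unsorted(py_grid)) stop("`py_grid` must be ascending", call. = FALSE)
  if (required_fraction <= 0 || required_fraction > 1)
    stop("`required_fraction` must be in (0, 1]", call. = FALSE)
  vapply(py_grid, assert_prob, 0, name = "py_grid")
  max_fail <- floor((1 - required_fraction) * replicates)
  point_seeds <- spawn_seeds(config$seed, length(py_grid))
  details <- data.frame(p_y = numeric(0), fraction = numeric(0),
                        replicates_run = integer(0), qualified = logical(0))
  threshold <- NA_real_
  for (i in seq_along(py_grid)) {
    config$drive$p_y <- py_grid[i]
    f <- erad_fraction(config, replicates, max_failures = max_fail,
                       root_seed = point_seeds[i])
    details[nrow(details) + 1L, ] <-
      list(py_grid[i], f$fraction, f$run, f$qualified)
    if (f$qualified) { threshold <- py_grid[i]; break }
  }
  structure(list(threshold = threshold, details = details,
                 required_fraction = required_fraction,
                 replicates = replicates),
            class = "threshold_result")
}

#' Coarse-to-fine eradication-threshold search
#'
#' Runs [find_eradication_threshold()] on a coarse grid over `[lo, hi]`,
#' then refines the bracket below the first qualifying coarse point on a
#' fine grid.
#'
#' @param config A [sim_config()].
#' @param lo,hi Search interval for `p_y`.
#' @param coarse_step,fine_step Grid resolutions of the two passes.
#' @param required_fraction,replicates Passed to
#'   [find_eradication_threshold()].
#' @param searches Number of independent coarse-to-fine searches; the
#'   reported threshold is their median (an odd count keeps it on the
#'   grid), which tames the Monte-Carlo noise of the all-replicates-
#'   eradicate indicator at small replicate counts.
#' @return A `threshold_result` whose `details` contains all passes.
#' @export
threshold_search <- function(config, lo = 0.5, hi = 1, coarse_step = 0.05,
                             fine_step = 0.01, required_fraction = 1,
                             replicates = 30, searches = 1) {
  if (searches > 1) {
    runs <- lapply(seq_len(searches), function(i) {
      cfg <- config
      cfg$seed <- config$seed + 1000L * (i - 1L)
      threshold_search(cfg, lo, hi, coarse_step, fine_step,
                       required_fraction, replicates, searches = 1)
    })
    ths <- vapply(runs, function(x) x$threshold, 0)
    return(structure(list(
      threshold = if (all(is.na(ths))) NA_real_
                  else stats::median(ths, na.rm = TRUE),
      thresholds = ths,
      details = do.call(rbind, lapply(runs, function(x) x$details)),
      required_fraction = required_fraction, replicates = replicates),
      class = "threshold_result"))
  }
  coarse <- find_eradication_threshold(
    config, seq(lo, hi, by = coarse_step), required_fraction, replicates)
  if (is.na(coarse$threshold)) return(coarse)
  f_lo <- max(lo, coarse$threshold - coarse_step + fine_step)
  if (f_lo >= coarse$threshold) return(coarse)
  fine_grid <- round(seq(f_lo, coarse$threshold, by = fine_step), 10)
  cfg <- config
  cfg$seed <- config$seed + 1L  # independent streams for the fine pass
  fine <- find_eradication_threshold(cfg, fine_grid, required_fraction,
                                     replicates)
  threshold <- if (is.na(fine$threshold)) coarse$threshold else fine$threshold
  structure(list(threshold = threshold,
                 details = rbind(coarse$details, fine$details),
                 required_fraction = required_fraction,
                 replicates = replicates),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> threshold = %s (required fraction %.2f, %d replicates/point)\n",
              format(x$threshold), x$required_fraction, x$replicates))
  print(x$details)
  invisible(x)
}
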