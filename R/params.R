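#' @useDynLib ychope, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rpois quantile plogis qlogis rbinom setNames predict
#' @importFrom utils write.csv read.csv packageVersion
NULL

# -- validation helpers ------------------------------------------------------

assert_prob <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("`%s` must be a single number in [%g, %g]", name, lo, hi),
         call. = FALSE)
  as.numeric(x)
}

assert_count <- function(x, name, lo = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo ||
      x != as.integer(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, lo),
         call. = FALSE)
  as.integer(x)
}

assert_choice <- function(x, name, choices) {
  if (!is.character(x) || length(x) != 1L || !(x %in% choices))
    stop(sprintf("`%s` must be one of: %s", name,
                 paste(choices, collapse = ", ")), call. = FALSE)
  x
}

# -- gene-drive parameters ---------------------------------------------------

#' Gene-drive parameters
#'
#' Parameters governing the homing mechanism and the Y-shredding cargo of the
#' autosomal drive. Defaults are the baseline parameterization of the model:
#' cutting probability \eqn{P_C = 0.95}, no NHEJ (\eqn{P_N = 0}), three
#' multiplexed homing gRNAs, per-mutation non-functionality probability
#' \eqn{P_{nf} = 1}, perfect Y-shredding (\eqn{P_Y = 1}), an XO-female
#' fertility multiplier of 0.6 and an X-transmission bias for XO mothers of
#' \eqn{P_{X|XO} = 0.66}.
#'
#' @param p_c Probability that the Cas endonuclease cuts a susceptible target
#'   site (per site, per homing event).
#' @param p_n Probability that a cut is repaired by non-homologous end-joining
#'   (NHEJ) rather than homing, conditional on at least one cut.
#' @param n_guides Number of multiplexed homing gRNAs, i.e. the number of
#'   target sites \eqn{S} carried by an intact wildtype allele.
#' @param p_nf Per-mutation probability that an NHEJ indel destroys the
#'   function of the gene hosting the drive (coding placement only).
#' @param placement Either `"noncoding"` (safe-harbour placement; allele
#'   functionality is irrelevant) or `"coding"` (placement inside a
#'   haploinsufficient gene; inheriting any non-functional allele is an early
#'   embryonic lethal).
#' @param p_y Y-shredding efficiency: probability that an XY zygote carrying
#'   at least one drive allele loses its Y chromosome and develops as an XO
#'   female.
#' @param xo_fertility Multiplier in \[0, 1\] applied to the expected litter
#'   size of XO mothers.
#' @param p_x_xo Probability that an XO mother transmits her X (rather than
#'   no sex chromosome) to an offspring; in \[0.5, 1\].
#' @return An object of class `drive_params`.
#' @examples
#' drive_params(p_y = 0.75, placement = "coding", p_n = 0.1)
#' @export
drive_params <- function(p_c = 0.95, p_n = 0, n_guides = 3, p_nf = 1,
                         placement = c("noncoding", "coding"), p_y = 1,
                         xo_fertility = 0.6, p_x_xo = 0.66) {
  placement <- match.arg(placement)
  out <- list(
    p_c = assert_prob(p_c, "p_c"),
    p_n = assert_prob(p_n, "p_n"),
    n_guides = assert_count(n_guides, "n_guides"),
    p_nf = assert_prob(p_nf, "p_nf"),
    placement = placement,
    p_y = assert_prob(p_y, "p_y"),
    xo_fertility = assert_prob(xo_fertility, "xo_fertility"),
    p_x_xo = assert_prob(p_x_xo, "p_x_xo", lo = 0.5)
  )
  structure(out, class = "drive_params")
}

#' Demographic parameters
#'
#' Mouse life-history and mating-system parameters. Defaults: carrying
#' capacity \eqn{K = 10000}, mean litter size \eqn{m = 6}, maximum annual
#' population growth rate \eqn{r_{max} = 7.76}, short-term monogamy
#' (\eqn{F_{max} = 1}) and 10 breeding cycles per year.
#'
#' Note the printed baseline for \eqn{r_{max}} is ambiguous between 7.97 and
#' 7.76 in the source material for this model; 7.76 is shipped as the default
#' and either value may be supplied.
#'
#' @param k Carrying capacity (individuals); must be an even integer >= 2.
#' @param litter_mean Mean offspring per litter for an XX mother.
#' @param r_max Maximum annual population growth rate (low-density limit).
#' @param f_max Maximum number of female mates per male per breeding cycle;
#'   1 = short-term monogamy, >1 = polygyny.
#' @param cycles_per_year Breeding cycles per year (10 for mice).
#' @return An object of class `demog_params`.
#' @export
demog_params <- function(k = 10000, litter_mean = 6, r_max = 7.76, f_max = 1,
                         cycles_per_year = 10) {
  if (!is.numeric(litter_mean) || length(litter_mean) != 1L ||
      is.na(litter_mean) || litter_mean <= 0)
    stop("`litter_mean` must be a single positive number", call. = FALSE)
  if (!is.numeric(r_max) || length(r_max) != 1L || is.na(r_max) || r_max <= 0)
    stop("`r_max` must be a single positive number", call. = FALSE)
  out <- list(
    k = assert_count(k, "k", lo = 2L),
    litter_mean = as.numeric(litter_mean),
    r_max = as.numeric(r_max),
    f_max = assert_count(f_max, "f_max"),
    cycles_per_year = assert_count(cycles_per_year, "cycles_per_year")
  )
  structure(out, class = "demog_params")
}

#' X-shredding Y-drive parameters
#'
#' Parameters of the comparator strategy: an X-shredding cassette integrated
#' on the Y chromosome and expressed during male meiosis.
#'
#' @param p_x Probability that a carrier male's germline X is destroyed
#'   during meiosis (so the male becomes germline YO).
#' @param p_y_yo Probability that a germline-YO male transmits a Y-bearing
#'   sperm; with `p_y_yo < 1` O-bearing sperm are possible and produce XO
#'   daughters.
#' @param per_gamete If `TRUE`, X-shredding is resolved independently for
#'   every gamete instead of once per male for life (default `FALSE`: a
#'   carrier male's germline-YO status is decided at his first breeding and
#'   is permanent).
#' @return An object of class `xshredder_params`.
#' @export
xshredder_params <- function(p_x = 1, p_y_yo = 1, per_gamete = FALSE) {
  structure(list(
    p_x = assert_prob(p_x, "p_x"),
    p_y_yo = assert_prob(p_y_yo, "p_y_yo"),
    per_gamete = isTRUE(per_gamete)
  ), class = "xshredder_params")
}

#' Simulation configuration
#'
#' Bundles drive, demographic and (optionally) X-shredder parameters with the
#' experiment settings: strategy, inoculum size, horizon, replicate count and
#' root seed.
#'
#' @param drive A [drive_params()] object.
#' @param demog A [demog_params()] object.
#' @param strategy `"ychope"` (autosomal Y-shredding homing drive) or
#'   `"xshredder"` (Y-linked X-shredding drive).
#' @param xshredder An [xshredder_params()] object (required when
#'   `strategy = "xshredder"`).
#' @param inoculum_size Number of drive-carrying founders added to the
#'   wildtype population: drive-heterozygous XX females for `"ychope"`,
#'   Y-linked-carrier XY males for `"xshredder"`.
#' @param years Simulation horizon in years.
#' @param replicates Number of replicate simulations for [run_replicates()].
#' @param seed Root seed; per-replicate streams are derived with
#'   [spawn_seeds()].
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(drive = drive_params(p_y = 1), inoculum_size = 100)
#' @export
sim_config <- function(drive = drive_params(), demog = demog_params(),
                       strategy = c("ychope", "xshredder"),
                       xshredder = NULL, inoculum_size = 100, years = 10,
                       replicates = 1000, seed = 1) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(drive, "drive_params"), inherits(demog, "demog_params"))
  if (strategy == "xshredder" && is.null(xshredder))
    xshredder <- xshredder_params()
  if (!is.null(xshredder)) stopifnot(inherits(xshredder, "xshredder_params"))
  if (!is.numeric(inoculum_size) || inoculum_size < 0 ||
      inoculum_size != as.integer(inoculum_size))
    stop("`inoculum_size` must be a non-negative integer", call. = FALSE)
  structure(list(
    drive = drive,
    demog = demog,
    strategy = strategy,
    xshredder = xshredder,
    inoculum_size = as.integer(inoculum_size),
    years = assert_count(years, "years"),
    replicates = assert_count(replicates, "replicates"),
    seed = assert_count(seed, "seed", lo = 0L)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$strategy, "strategy\n")
  cat(sprintf("  drive: P_C=%g P_N=%g nGuides=%d P_nf=%g P_Y=%g placement=%s\n",
              x$drive$p_c, x$drive$p_n, x$drive$n_guides, x$drive$p_nf,
              x$drive$p_y, x$drive$placement))
  cat(sprintf("  demog: K=%d m=%g r_max=%g F_max=%d cycles/yr=%d\n",
              x$demog$k, x$demog$litter_mean, x$demog$r_max, x$demog$f_max,
              x$demog$cycles_per_year))
  if (!is.null(x$xshredder))
    cat(sprintf("  xshredder: P_X=%g P_Y|YO=%g\n",
                x$xshredder$p_x, x$xshredder$p_y_yo))
  cat(sprintf("  inoculum=%d years=%d replicates=%d seed=%d\n",
              x$inoculum_size, x$years, x$replicates, x$seed))
  invisible(x)
}
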