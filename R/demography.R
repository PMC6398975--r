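# Mating system, litters, density-dependent survival and aging.

#' Allocate mating pairs for one breeding cycle
#'
#' Females are processed in random order; each samples a mate uniformly from
#' the pool of males that have not yet reached `max_mates` females this
#' cycle, and a male leaves the pool once he reaches his cap. Females facing
#' an empty pool remain unmated. Each female appears in at most one pair
#' (no multiple paternity).
#'
#' @param females,males Integer vectors of female and male indices (either
#'   may be empty).
#' @param max_mates Maximum female mates per male per cycle (`F_max`).
#' @return An object of class `mate_pairing`: a data frame with columns
#'   `female` and `male`, one row per pair.
#' @examples
#' set.seed(1)
#' allocate_mates(1:5, 6:7, max_mates = 3)  # 5 pairs, capacity 6 >= 5
#' @export
allocate_mates <- function(females, males, max_mates) {
  max_mates <- assert_count(max_mates, "max_mates")
  nf <- length(females)
  nm <- length(males)
  if (nf == 0L || nm == 0L)
    return(structure(data.frame(female = integer(0), male = integer(0)),
                     class = c("mate_pairing", "data.frame")))
  females <- females[sample.int(nf)]
  pool <- males
  used <- integer(nm)          # mates so far, indexed like `pool`
  f_out <- integer(nf); m_out <- integer(nf); np <- 0L
  psize <- nm
  for (f in females) {
    if (psize == 0L) break
    k <- sample.int(psize, 1L)
    np <- np + 1L
    f_out[np] <- f; m_out[np] <- pool[k]
    used[k] <- used[k] + 1L
    if (used[k] >= max_mates) {      # swap-remove exhausted male
      pool[k] <- pool[psize]; used[k] <- used[psize]
      psize <- psize - 1L
    }
  }
  structure(data.frame(female = f_out[seq_len(np)], male = m_out[seq_len(np)]),
            class = c("mate_pairing", "data.frame"))
}

#' Expected litter size of a mother
#'
#' `litter_mean` for XX mothers, `litter_mean * xo_fertility` for sub-fertile
#' XO mothers.
#'
#' @param mother An [individual()] (must be female).
#' @param drive A [drive_params()] (supplies `xo_fertility`).
#' @param demog A [demog_params()] (supplies `litter_mean`).
#' @return A non-negative number.
#' @export
expected_litter <- function(mother, drive, demog) {
  if (!is_female(mother))
    stop("`mother` must be female", call. = FALSE)
  m <- demog$litter_mean
  if (mother$allosomes == "XO") m * drive$xo_fertility else m
}

#' Generate one litter
#'
#' Realized litter size is Poisson with mean [expected_litter()]. Each
#' conception passes through [transmit_gametes()] and then [shred_y()];
#' embryonic deaths (YO conceptions and, under coding placement, inherited
#' non-functional alleles) are discarded, shrinking the realized litter.
#'
#' @param mother,father [individual()]s.
#' @param drive A [drive_params()].
#' @param demog A [demog_params()].
#' @param tables Optional precomputed homing tables.
#' @return A list of newborn [individual()]s (age 0).
#' @export
make_litter <- function(mother, father, drive, demog, tables = NULL) {
  if (is.null(tables)) tables <- make_transition_tables(drive)
  n <- rpois(1, expected_litter(mother, drive, demog))
  out <- vector("list", n)
  kept <- 0L
  for (i in seq_len(n)) {
    z <- transmit_gametes(mother, father, drive, tables)
    if (z$died) next
    carries <- is_drive(z$allele_m) || is_drive(z$allele_p)
    allos <- shred_y(z$allosomes, carries, drive)
    kept <- kept + 1L
    out[[kept]] <- individual(allos, z$allele_m, z$allele_p, age = 0L)
  }
  out[seq_len(kept)]
}

#' Density-dependent survival probability
#'
#' Per-cycle survival is a two-parameter logistic in population size,
#' \eqn{s(n) = 1 / (1 + \exp(a + b n))}, calibrated so that under an equal
#' sex ratio and full mating the expected per-cycle growth factor
#' \eqn{(1 + m/2)\,s(n)} equals 1 at the carrying capacity \eqn{n = K}
#' (stability) and equals \eqn{\exp(r_{max}/\mathrm{cycles})} as
#' \eqn{n \to 0} (maximum growth). Monotonically decreasing in `n`.
#'
#' @param n Population size (vectorised, `n >= 0`).
#' @param demog A [demog_params()].
#' @return Survival probabilities in (0, 1).
#' @examples
#' survival_probability(10000, demog_params())  # 1/(1 + 6/2) = 0.25
#' @export
survival_probability <- function(n, demog) {
  ab <- calibrate_survival(demog)
  plogis(-(ab[["a"]] + ab[["b"]] * n))
}

# Solve the logistic coefficients from the two endpoint constraints.
# With clamp = TRUE (the engine's setting) an unattainable low-density
# constraint saturates survival at 1 instead of erroring: the realized
# maximum growth rate is then capped by the litter size at
# cycles * log(1 + m/2), which matters only for sensitivity-analysis
# parameter combinations with small litters and large r_max.
calibrate_survival <- function(demog, clamp = FALSE) {
  lam1 <- 1 + demog$litter_mean / 2                     # births factor
  s_k <- 1 / lam1                                       # stability at K
  s_0 <- exp(demog$r_max / demog$cycles_per_year) / lam1
  if (clamp) s_0 <- min(s_0, 1 - 1e-9)
  if (s_0 >= 1 || s_0 <= 0 || s_k <= 0 || s_k >= 1 || s_0 <= s_k)
    stop(sprintf(paste0("infeasible survival calibration: required s(0)=%.4f",
                        " and s(K)=%.4f must lie in (0, 1); increase",
                        " litter_mean or decrease r_max"), s_0, s_k),
         call. = FALSE)
  a <- qlogis(1 - s_0)                #   s(0)   = 1/(1+exp(a))
  b <- (qlogis(1 - s_k) - a) / demog$k
  c(a = a, b = b)
}

#' Apply density-dependent mortality and aging
#'
#' Every individual (newborns included) survives independently with
#' probability `survival_probability(n_density, demog)`; survivors age by
#' one cycle. `n_density` is the pre-breeding census size of the cycle (the
#' population that entered the breeding cycle), the density at which the
#' stability-at-K calibration holds.
#'
#' @param population List of [individual()]s (adults plus newborns).
#' @param n_density Population size used as the density argument.
#' @param demog A [demog_params()].
#' @return The surviving population, ages incremented.
#' @export
apply_mortality_and_age <- function(population, n_density, demog) {
  if (length(population) == 0L) return(population)
  s <- survival_probability(n_density, demog)
  keep <- runif(length(population)) < s
  out <- population[keep]
  lapply(out, function(ind) { ind$age <- ind$age + 1L; ind })
}
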