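# Inheritance operations at the level of single matings. These R functions
# define the model semantics; the compiled engine reproduces them (from the
# same homing tables) for whole-population runs.

#' Construct an individual
#'
#' @param allosomes `"XX"`, `"XY"` or `"XO"`. YO is never constructible:
#'   YO conceptions die as early embryos and are discarded before birth.
#' @param allele_m,allele_p Maternal and paternal autosomal [allele()]s at
#'   the drive locus.
#' @param age Age in breeding cycles.
#' @param y_drive Does the Y chromosome carry an X-shredding cassette
#'   (xshredder strategy only)?
#' @return An object of class `individual`; `$sex` is derived from the
#'   allosomes (XY is male; XX and XO are female).
#' @export
individual <- function(allosomes = c("XX", "XY", "XO"),
                       allele_m = allele("wildtype", 3),
                       allele_p = allele("wildtype", 3),
                       age = 0L, y_drive = FALSE) {
  allosomes <- match.arg(allosomes)
  structure(list(
    allosomes = allosomes,
    allele_m = allele_m,
    allele_p = allele_p,
    age = as.integer(age),
    y_drive = isTRUE(y_drive),
    germline_yo = NA,  # xshredder: lifetime germline state, set at 1st breeding
    sex = if (allosomes == "XY") "male" else "female"
  ), class = "individual")
}

is_female <- function(ind) ind$sex == "female"

n_drive_alleles <- function(ind)
  as.integer(is_drive(ind$allele_m)) + as.integer(is_drive(ind$allele_p))

# Is this parent eligible for germline homing? Exactly one drive allele and
# one wildtype allele with >= 1 susceptible site. GG, GR (0 sites), WW etc.
# pass through unmodified.
homing_eligible <- function(a1, a2) {
  (is_drive(a1) && !is_drive(a2) && a2$sites >= 1L) ||
  (is_drive(a2) && !is_drive(a1) && a1$sites >= 1L)
}

#' Germline homing in a heterozygous parent
#'
#' Applies one per-gamete homing event to an allele pair. If the pair is a
#' drive/wildtype heterozygote (the wildtype allele having at least one
#' susceptible site), the wildtype allele is replaced by a draw from the
#' homing transition distribution: conversion to the drive, or an NHEJ/no-cut
#' outcome with `j <= s` susceptible sites, a deletion flag, and (under
#' coding placement) functionality sampled with per-mutation loss probability
#' `p_nf` (deletions always cause loss of function). Any other pair is
#' returned unchanged. Homing is resampled independently for every offspring.
#'
#' @param allele_pair List of two [allele()]s.
#' @param params A [drive_params()].
#' @param tables Optional precomputed result of `make_transition_tables`
#'   (recomputed if `NULL`).
#' @return A list of two alleles.
#' @export
germline_homing <- function(allele_pair, params, tables = NULL) {
  a1 <- allele_pair[[1]]; a2 <- allele_pair[[2]]
  if (!homing_eligible(a1, a2)) return(allele_pair)
  w_first <- !is_drive(a1)
  w <- if (w_first) a1 else a2
  if (is.null(tables)) tables <- make_transition_tables(params)
  dist <- tables[[w$sites]]
  u <- runif(1)
  k <- findInterval(u, dist$cum) + 1L
  k <- min(k, length(dist$codes))
  code <- dist$codes[k]
  new_w <- if (code == -1L) {
    allele("drive")
  } else if (code == -2L) {
    # non-functional under coding placement (lethal if inherited)
    allele("resistant", sites = 0L, deletion = TRUE, functional = FALSE)
  } else {
    a <- allele_from_code(code)
    a$deletion <- a$deletion || w$deletion
    a
  }
  if (code == -2L) {
    # keep true j/deletion bookkeeping for the non-functional allele: resample
    # j and deletion from the conditional table is unnecessary for dynamics
    # (the allele is lethal when inherited); mark it resistant/non-functional.
    new_w$functional <- FALSE
  }
  if (w_first) list(new_w, a2) else list(a1, new_w)
}

#' Transmit gametes to one conception
#'
#' Applies per-parent germline homing, then allocates one autosomal allele
#' from each parent (Bernoulli, p = 0.5) and one allosome from each parent:
#' XX mothers always transmit an X; XO mothers transmit their X with
#' probability `p_x_xo` and nothing (O) otherwise; fathers transmit X or Y
#' with probability 0.5 each. A paternal Y meeting a maternal O is a YO
#' conception and dies as an early embryo. Under coding placement,
#' inheriting any non-functional allele is also an early embryonic lethal.
#'
#' @param mother,father [individual()]s (mother female XX/XO, father male XY).
#' @param params A [drive_params()].
#' @param tables Optional precomputed homing tables.
#' @return A list with `died` (logical; `reason` one of `"YO"`,
#'   `"nonfunctional"` when `TRUE`) or, for a viable conception, `allosomes`
#'   (`"XX"`, `"XY"` or `"XO"`), `allele_m`, `allele_p`.
#' @export
transmit_gametes <- function(mother, father, params, tables = NULL) {
  if (!is_female(mother) || is_female(father))
    stop("`mother` must be female (XX/XO) and `father` male (XY)",
         call. = FALSE)
  if (is.null(tables)) tables <- make_transition_tables(params)

  pick <- function(pair) if (runif(1) < 0.5) pair[[1]] else pair[[2]]
  am <- pick(germline_homing(list(mother$allele_m, mother$allele_p),
                             params, tables))
  ap <- pick(germline_homing(list(father$allele_m, father$allele_p),
                             params, tables))

  mat <- if (mother$allosomes == "XX") "X"
         else if (runif(1) < params$p_x_xo) "X" else "O"
  pat <- if (runif(1) < 0.5) "X" else "Y"

  if (mat == "O" && pat == "Y")
    return(list(died = TRUE, reason = "YO"))
  if (params$placement == "coding" && (!am$functional || !ap$functional))
    return(list(died = TRUE, reason = "nonfunctional"))

  allos <- if (pat == "Y") "XY" else if (mat == "O") "XO" else "XX"
  list(died = FALSE, allosomes = allos, allele_m = am, allele_p = ap)
}

#' Zygotic Y-shredding
#'
#' In an XY zygote carrying at least one drive allele, the Y chromosome is
#' shredded with probability `p_y`, converting the zygote to an XO female.
#' All other inputs are returned unchanged.
#'
#' @param genotype `"XX"`, `"XY"` or `"XO"`.
#' @param carries_drive Does the zygote carry >= 1 drive allele?
#' @param params A [drive_params()].
#' @return The (possibly shredded) allosome genotype.
#' @export
shred_y <- function(genotype, carries_drive, params) {
  if (genotype == "XY" && isTRUE(carries_drive) && runif(1) < params$p_y)
    "XO"
  else
    genotype
}
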