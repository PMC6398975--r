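# Per-mating inheritance: germline homing draws, gamete transmission,
# zygotic Y-shredding.

test_that("germline_homing passes non-eligible pairs through", {
  p <- drive_params(p_c = 1, p_n = 0.5)
  gg <- list(allele("drive"), allele("drive"))
  expect_identical(germline_homing(gg, p), gg)
  gr <- list(allele("drive"), allele("resistant", 0))
  expect_identical(germline_homing(gr, p), gr)
  ww <- list(allele("wildtype", 3), allele("wildtype", 3))
  expect_identical(germline_homing(ww, p), ww)
})

test_that("certain homing converts the wildtype allele", {
  p <- drive_params(p_c = 1, p_n = 0)
  set.seed(1)
  for (i in 1:20) {
    out <- germline_homing(list(allele("wildtype", 3), allele("drive")), p)
    expect_equal(out[[1]]$kind, "drive")
    expect_equal(out[[2]]$kind, "drive")
    # and in the other order
    out2 <- germline_homing(list(allele("drive"), allele("wildtype", 3)), p)
    expect_equal(out2[[2]]$kind, "drive")
  }
})

test_that("Monte-Carlo homing frequency matches the exact table", {
  p <- drive_params(p_c = 0.95, p_n = 0.1)
  tables <- ychope:::make_transition_tables(p)
  ht <- build_homing_table(3, p)
  n <- 1e5
  set.seed(42)
  pair <- list(allele("wildtype", 3), allele("drive"))
  homed <- 0L
  j_counts <- setNames(numeric(4), 0:3)
  for (i in seq_len(n)) {
    out <- germline_homing(pair, p, tables)[[1]]
    if (out$kind == "drive") homed <- homed + 1L
    else j_counts[as.character(out$sites)] <-
        j_counts[as.character(out$sites)] + 1
  }
  se <- sqrt(ht$homing_prob * (1 - ht$homing_prob) / n)
  expect_lt(abs(homed / n - ht$homing_prob), 3 * se)
  # non-homing outcome distribution over j, 3.5 MC SEs each
  for (j in 0:3) {
    pj <- sum(ht$transitions$prob[ht$transitions$j == j])
    sej <- sqrt(max(pj * (1 - pj), 1e-12) / n)
    expect_lt(abs(j_counts[as.character(j)] / n - pj), 3.5 * sej + 1e-9)
  }
})

test_that("XO mothers transmit X with probability p_x_xo", {
  p <- drive_params(p_x_xo = 0.66)
  mo <- individual("XO")
  fa <- individual("XY")
  n <- 1e5
  set.seed(7)
  tables <- ychope:::make_transition_tables(p)
  allos <- character(n)
  died_yo <- 0L
  for (i in seq_len(n)) {
    z <- transmit_gametes(mo, fa, p, tables)
    if (z$died) { died_yo <- died_yo + (z$reason == "YO"); allos[i] <- "dead" }
    else allos[i] <- z$allosomes
  }
  # maternal X frequency = P(X) = 0.66; YO deaths = 0.34 * 0.5 = 0.17
  got_x <- sum(allos %in% c("XX", "XY")) / n
  expect_lt(abs(got_x - 0.66), 3 * sqrt(0.66 * 0.34 / n))
  expect_lt(abs(died_yo / n - 0.17), 3 * sqrt(0.17 * 0.83 / n))
})

test_that("drive-free matings give a 50/50 sex ratio", {
  p <- drive_params()
  mo <- individual("XX")
  fa <- individual("XY")
  set.seed(3)
  n <- 2e4
  xy <- 0L
  for (i in seq_len(n)) {
    z <- transmit_gametes(mo, fa, p)
    expect_false(z$died)
    xy <- xy + (z$allosomes == "XY")
  }
  expect_lt(abs(xy / n - 0.5), 3 * sqrt(0.25 / n))
})

test_that("same-sex pairs are rejected", {
  p <- drive_params()
  expect_error(transmit_gametes(individual("XY"), individual("XY"), p),
               "female")
  expect_error(transmit_gametes(individual("XX"), individual("XX"), p),
               "male")
})

test_that("coding placement kills conceptions inheriting non-functional alleles", {
  # P_C = 1, P_N = 1, P_nf = 1, s = 1: the mother's W allele always mutates
  # to a non-functional resistant allele; half of conceptions inherit it.
  p <- drive_params(p_c = 1, p_n = 1, n_guides = 1, p_nf = 1,
                    placement = "coding")
  mo <- individual("XX", allele("wildtype", 1), allele("drive"))
  fa <- individual("XY", allele("wildtype", 1), allele("wildtype", 1))
  set.seed(11)
  n <- 4000
  dead <- 0L
  for (i in seq_len(n)) {
    z <- transmit_gametes(mo, fa, p)
    if (z$died) {
      dead <- dead + 1L
      expect_equal(z$reason, "nonfunctional")
    } else {
      # survivors got the drive from the mother
      expect_equal(z$allele_m$kind, "drive")
    }
  }
  expect_lt(abs(dead / n - 0.5), 3 * sqrt(0.25 / n))
})

test_that("shred_y converts drive-carrying XY zygotes and nothing else", {
  certain <- drive_params(p_y = 1)
  never <- drive_params(p_y = 0)
  set.seed(5)
  expect_equal(shred_y("XY", TRUE, certain), "XO")
  expect_equal(shred_y("XY", FALSE, certain), "XY")
  expect_equal(shred_y("XX", TRUE, certain), "XX")
  expect_equal(shred_y("XO", TRUE, certain), "XO")
  expect_equal(shred_y("XY", TRUE, never), "XY")
  # intermediate efficiency: frequency check
  half <- drive_params(p_y = 0.5)
  got <- vapply(1:4000, function(i) shred_y("XY", TRUE, half), "")
  expect_lt(abs(mean(got == "XO") - 0.5), 3 * sqrt(0.25 / 4000))
})
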