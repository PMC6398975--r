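# Homing transition tables: exact values against an independent
# enumeration oracle, and the normalization/limit properties.

test_that("worked examples match the exact enumeration", {
  # s = 3, P_C = 0.95, no NHEJ: homing whenever >= 1 cut
  ht <- build_homing_table(3, drive_params(p_c = 0.95, p_n = 0))
  expect_equal(ht$homing_prob, 1 - 0.05^3, tolerance = 1e-12)

  # no cutting possible: stay at s with certainty
  ht0 <- build_homing_table(2, drive_params(p_c = 0, p_n = 0.3))
  expect_equal(ht0$homing_prob, 0)
  stay <- ht0$transitions[ht0$transitions$j == 2 & ht0$transitions$d == 0, ]
  expect_equal(stay$prob, 1)

  # s = 1, always NHEJ: resistant with one mutation w.p. 0.95, else unchanged
  ht1 <- build_homing_table(1, drive_params(p_c = 0.95, p_n = 1))
  expect_equal(ht1$homing_prob, 0)
  expect_equal(ht1$transitions$prob[ht1$transitions$j == 0], 0.95)
  expect_equal(ht1$transitions$prob[ht1$transitions$j == 1], 0.05)
  expect_false(any(ht1$transitions$deletion))  # single cuts never delete
})

test_that("tables agree with the brute-force oracle over a parameter grid", {
  for (s in 1:5) {
    for (p_c in c(0.2, 0.7, 0.95)) {
      for (p_n in c(0, 0.1, 0.5, 1)) {
        params <- drive_params(p_c = p_c, p_n = p_n, n_guides = 5)
        ht <- build_homing_table(s, params)
        orc <- oracle_homing(s, p_c, p_n)
        expect_equal(ht$homing_prob, orc$homing, tolerance = 1e-12)
        # full normalization, exact
        expect_equal(ht$homing_prob + sum(ht$transitions$prob), 1,
                     tolerance = 1e-12)
        # distribution over remaining-site counts matches the oracle
        pj <- vapply(0:s, function(j)
          sum(ht$transitions$prob[ht$transitions$j == j]), 0)
        expect_equal(pj, unname(orc$pj), tolerance = 1e-12)
      }
    }
  }
})

test_that("homing probability follows the closed form (1-P_N)(1-(1-P_C)^s)", {
  for (s in 1:4) {
    ht <- build_homing_table(s, drive_params(p_c = 0.8, p_n = 0.25,
                                             n_guides = 4))
    expect_equal(ht$homing_prob, 0.75 * (1 - 0.2^s), tolerance = 1e-12)
  }
})

test_that("deletion bookkeeping follows the span rule", {
  # s = 3: cutting sites {1,3} deletes site 2 -> j = 0 with deletion;
  # cutting {1,2} leaves site 3 -> j = 1 with deletion
  ht <- build_homing_table(3, drive_params(p_c = 0.5, p_n = 1))
  tr <- ht$transitions
  expect_true(any(tr$deletion & tr$j == 1))       # adjacent pair cut
  expect_true(any(tr$deletion & tr$j == 0))
  # deletions require >= 2 cuts
  expect_true(all(tr$d[tr$deletion] >= 2))
  # j = s - 1 outcomes with one mutation never carry a deletion
  expect_false(any(tr$deletion[tr$d == 1]))
})

test_that("invalid inputs are rejected", {
  p <- drive_params(n_guides = 3)
  expect_error(build_homing_table(0, p), "must be in")
  expect_error(build_homing_table(4, p), "must be in")
  expect_error(drive_params(p_c = 1.2), "p_c")
  expect_error(drive_params(p_n = -0.1), "p_n")
  expect_error(drive_params(p_x_xo = 0.3), "p_x_xo")
  expect_error(drive_params(n_guides = 0), "n_guides")
})

test_that("allele-level outcome distributions respect placement", {
  coding <- drive_params(p_c = 0.9, p_n = 0.3, n_guides = 3, p_nf = 0.5,
                         placement = "coding")
  noncod <- drive_params(p_c = 0.9, p_n = 0.3, n_guides = 3, p_nf = 0.5,
                         placement = "noncoding")
  for (s in 1:3) {
    dc <- homing_outcome_dist <- ychope:::homing_outcome_dist(s, coding)
    dn <- ychope:::homing_outcome_dist(s, noncod)
    expect_equal(sum(dc$probs), 1, tolerance = 1e-12)
    expect_equal(sum(dn$probs), 1, tolerance = 1e-12)
    expect_false(any(dn$codes == -2L))  # noncoding never produces lethals
  }
  # coding, p_nf = 1: every mutated outcome is non-functional
  lethal <- drive_params(p_c = 0.9, p_n = 1, n_guides = 3, p_nf = 1,
                         placement = "coding")
  d1 <- ychope:::homing_outcome_dist(3, lethal)
  viable <- d1$codes[d1$codes > 0]
  # the only viable non-homing outcome is the unchanged allele (no cut)
  expect_equal(viable, 1L + 2L * 3L)
})
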