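# Latin hypercube design and the boosted-regression-tree emulator.

test_that("LHS stratification is exact for continuous parameters", {
  r <- data.frame(name = "u", dist = "uniform", lo = 0, hi = 1)
  d <- lhs_sample(r, n = 10, seed = 4)
  s <- sort(d$u)
  # exactly one sample per decile
  expect_equal(findInterval(s, seq(0, 1, by = 0.1),
                            rightmost.closed = TRUE), 1:10)
  # and for every continuous column of the shipped ranges
  full <- lhs_sample(sensitivity_ranges(), n = 50, seed = 4)
  rg <- sensitivity_ranges()
  for (i in which(rg$dist == "uniform")) {
    x <- sort((full[[rg$name[i]]] - rg$lo[i]) / (rg$hi[i] - rg$lo[i]))
    expect_equal(findInterval(x, seq(0, 1, length.out = 51),
                              rightmost.closed = TRUE), 1:50)
  }
})

test_that("discrete parameters cover their support uniformly", {
  d <- lhs_sample(n = 500, seed = 9)
  tab <- table(factor(d$n_guides, levels = 1:5))
  expect_true(all(tab > 0))
  expect_lt(max(abs(tab / 500 - 0.2)), 0.08)  # ~4 binomial SDs
  expect_true(all(d$f_max %in% 1:10))
})

test_that("designs are reproducible and validated", {
  expect_identical(lhs_sample(n = 20, seed = 1), lhs_sample(n = 20, seed = 1))
  expect_false(identical(lhs_sample(n = 20, seed = 1),
                         lhs_sample(n = 20, seed = 2)))
  expect_error(lhs_sample(n = 1), ">= 2")
  bad <- data.frame(name = "x", dist = "uniform", lo = 1, hi = 0)
  expect_error(lhs_sample(bad, n = 10), "invalid")
})

test_that("run_design is deterministic given the base seed", {
  d <- lhs_sample(n = 6, seed = 2)
  base <- sim_config(drive = drive_params(placement = "coding"),
                     demog = demog_params(k = 150),
                     inoculum_size = 2, replicates = 1, seed = 7)
  y1 <- run_design(d, base)
  y2 <- run_design(d, base)
  expect_identical(y1, y2)
  expect_true(all(y1 %in% 0:1))
})

test_that("the emulator recovers a single-variable generative truth", {
  d <- lhs_sample(n = 1500, seed = 3)
  y <- as.integer(d$p_y > 0.9)
  em <- fit_emulator(d, y, seed = 2, max_trees = 1500)
  expect_equal(sum(em$influence), 100, tolerance = 1e-6)
  expect_true(all(em$influence >= 0))
  expect_gt(em$influence["p_y"], 90)
  expect_gt(em$cv_auc, 0.98)
  # near-step partial dependence at 0.9
  pd <- partial_dependence(em, "p_y", grid_n = 41)
  expect_lt(mean(pd$prob[pd$p_y < 0.85]), 0.1)
  expect_gt(mean(pd$prob[pd$p_y > 0.95]), 0.9)
  # marginal mode shows the same step
  pdm <- partial_dependence(em, "p_y", grid_n = 11, mode = "marginal")
  expect_gt(pdm$prob[11] - pdm$prob[1], 0.7)
})

test_that("permuted labels spread influence roughly uniformly", {
  d <- lhs_sample(n = 1200, seed = 5)
  y <- as.integer(d$p_y > 0.9)
  set.seed(6)
  infl <- replicate(3, {
    fit_emulator(d, sample(y), seed = 1, max_trees = 300,
                 patience = 100)$influence
  })
  # expected influence per parameter ~ 10%; no parameter dominates on average
  expect_lt(max(rowMeans(infl)), 25)
})

test_that("emulator input contracts are enforced", {
  d <- lhs_sample(n = 100, seed = 1)
  expect_error(fit_emulator(d, rep(0, 100)), "degenerate")
  expect_error(fit_emulator(d, rep(1, 100)), "degenerate")
  expect_error(fit_emulator(d, c(rep(0, 50), rep(2, 50))), "binary")
  expect_error(fit_emulator(d, rep(0:1, 10)), "one value per design row")
})

test_that("partial dependence validates names and honours clamping", {
  d <- lhs_sample(n = 800, seed = 8)
  y <- as.integer(d$f_max <= 3)
  em <- fit_emulator(d, y, seed = 3, max_trees = 800)
  expect_error(partial_dependence(em, "nope"), "unknown parameter")
  pd <- partial_dependence(em, "f_max")
  expect_equal(pd$f_max, 1:10)  # discrete support
  expect_gt(mean(pd$prob[pd$f_max <= 2]), mean(pd$prob[pd$f_max >= 8]))
  # clamp values are honoured: conditioning on p_y should not error and
  # produce probabilities in [0, 1]
  pd2 <- partial_dependence(em, "f_max", fixed_values = list(p_y = 0.8))
  expect_true(all(pd2$prob >= 0 & pd2$prob <= 1))
})

test_that("convergence_check compares nested refits", {
  d <- lhs_sample(n = 900, seed = 11)
  y <- as.integer(d$p_y > 0.85)
  expect_error(convergence_check(d, y, 500), "length >= 2")
  expect_error(convergence_check(d, y, c(900, 500)), "ascending")
  expect_error(convergence_check(d, y, c(500, 1200)), "exceeds")
  cc <- convergence_check(d, y, c(450, 900, 900), max_trees = 500, seed = 4)
  expect_equal(nrow(cc$table), 3L)
  # identical sizes give identical fits, so the check converges exactly
  expect_equal(unlist(cc$table[2, -(1:3)]), unlist(cc$table[3, -(1:3)]))
  expect_true(cc$converged)
  expect_equal(cc$max_abs_diff, 0)
})
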