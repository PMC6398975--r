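# Experiment drivers: initialization, the five-stage cycle, determinism,
# conservation, replicate summaries and the agreement between the compiled
# engine and the pure-R reference implementation.

test_that("initialize_population builds the stated founders", {
  cfg <- small_config(k = 1000, inoculum = 10)
  pop <- initialize_population(cfg)
  expect_length(pop, 1010L)
  sexes <- vapply(pop, function(i) i$sex, "")
  expect_equal(sum(sexes == "female"), 510L)
  wg <- vapply(pop, function(i)
    xor(i$allele_m$kind == "drive", i$allele_p$kind == "drive"), NA)
  expect_equal(sum(wg), 10L)
  expect_true(all(vapply(pop[wg], function(i) i$allosomes == "XX", NA)))

  xcfg <- small_config(k = 1000, inoculum = 10, strategy = "xshredder",
                       xshredder = xshredder_params())
  xpop <- initialize_population(xcfg)
  yd <- vapply(xpop, function(i) i$y_drive, NA)
  expect_equal(sum(yd), 10L)
  expect_true(all(vapply(xpop[yd], function(i) i$allosomes == "XY", NA)))

  expect_error(initialize_population(
    sim_config(demog = demog_params(k = 999), inoculum_size = 0)), "even")
  # inoculum 0: pure wildtype control
  pop0 <- initialize_population(small_config(k = 200, inoculum = 0))
  expect_length(pop0, 200L)
  expect_true(all(vapply(pop0, function(i)
    i$allele_m$kind == "wildtype", NA)))
})

test_that("fixed seeds give bitwise-identical results", {
  cfg <- small_config(k = 400, inoculum = 8, p_y = 0.5, p_n = 0.1, years = 3)
  a <- run_simulation(cfg, seed = 99)
  b <- run_simulation(cfg, seed = 99)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$eradication_cycle, b$eradication_cycle)
  c <- run_simulation(cfg, seed = 100)
  expect_false(identical(a$trajectory, c$trajectory))
})

test_that("genotype bookkeeping is conserved on every cycle", {
  cfg <- small_config(k = 600, inoculum = 12, p_y = 0.7, p_n = 0.1,
                      placement = "noncoding", years = 5, f_max = 3)
  res <- run_simulation(cfg, seed = 21)
  expect_conserved(res$trajectory)
  # xshredder runs too
  xcfg <- small_config(k = 600, inoculum = 12, years = 5, f_max = 3,
                       strategy = "xshredder",
                       xshredder = xshredder_params(p_x = 0.8, p_y_yo = 0.9))
  xres <- run_simulation(xcfg, seed = 21)
  expect_conserved(xres$trajectory)
})

test_that("the empty population is absorbing and all-female pools stall", {
  cfg <- small_config(k = 200)
  expect_identical(step_cycle(list(), cfg), list())
  females <- replicate(30, individual("XX"), simplify = FALSE)
  set.seed(8)
  out <- step_cycle(females, cfg)
  # no births possible; survivors are a subset of the 30 females, aged
  expect_lte(length(out), 30L)
  expect_true(all(vapply(out, function(i) i$sex == "female", NA)))
  expect_true(all(vapply(out, function(i) i$age, 0L) == 1L))
})

test_that("drive-free populations stay near K (calibration identity)", {
  cfg <- small_config(k = 2000, inoculum = 0, years = 5)
  finals <- vapply(1:10, function(r)
    run_simulation(cfg, seed = 100 + r)$trajectory$N[51], 0)
  expect_lt(abs(mean(finals) - 2000) / 2000, 0.05)
})

test_that("eradication flag and cycle agree with the trajectory", {
  cfg <- small_config(k = 200, inoculum = 20, p_y = 1, years = 10)
  res <- run_simulation(cfg, seed = 12)
  expect_true(res$eradicated)
  tr <- res$trajectory
  expect_equal(tr$N[res$eradication_cycle + 1L], 0L)
  expect_gt(tr$N[res$eradication_cycle], 0L)
  # zeros persist after eradication
  expect_true(all(tr$N[tr$cycle >= res$eradication_cycle] == 0L))
})

test_that("run_replicates summarizes eradication and trajectories", {
  cfg <- small_config(k = 300, inoculum = 30, p_y = 1, years = 6, seed = 5)
  rs <- run_replicates(cfg, replicates = 8)
  expect_equal(rs$eradication_probability, mean(rs$eradicated))
  expect_length(rs$seeds, 8L)
  expect_equal(anyDuplicated(rs$seeds), 0L)
  sm <- rs$trajectory_summary$N
  expect_true(all(sm$lo <= sm$mean + 1e-9 & sm$mean <= sm$hi + 1e-9))
  # replicates = 1 degenerates to the single run
  rs1 <- run_replicates(cfg, replicates = 1)
  one <- run_simulation(cfg, seed = rs1$seeds[1])
  expect_equal(rs1$trajectory_summary$N$mean, as.numeric(one$trajectory$N))
})

test_that("compiled and reference engines agree statistically", {
  cfg <- small_config(k = 200, inoculum = 6, p_y = 0.9, p_n = 0.1,
                      placement = "noncoding", years = 2)
  n_rep <- 12
  traj_cpp <- sapply(1:n_rep, function(r)
    run_simulation(cfg, seed = 300 + r, engine = "cpp")$trajectory$N)
  traj_r <- sapply(1:n_rep, function(r)
    run_simulation(cfg, seed = 600 + r, engine = "r")$trajectory$N)
  m_cpp <- rowMeans(traj_cpp); m_r <- rowMeans(traj_r)
  # pooled relative deviation of the mean trajectories stays small
  expect_lt(mean(abs(m_cpp - m_r) / pmax(m_cpp, 1)), 0.15)
  # carrier spread agrees too
  c_cpp <- mean(sapply(1:n_rep, function(r)
    run_simulation(cfg, seed = 300 + r)$trajectory$carriers[21]))
  c_r <- mean(sapply(1:n_rep, function(r)
    run_simulation(cfg, seed = 600 + r, engine = "r")$trajectory$carriers[21]))
  expect_lt(abs(c_cpp - c_r), 0.5 * max(c_cpp, c_r) + 5)
})

test_that("eradication probability is non-decreasing in shredding efficiency", {
  fracs <- vapply(c(0.3, 0.7, 1), function(py) {
    cfg <- small_config(k = 300, inoculum = 30, p_y = py, years = 8,
                        seed = 41)
    mean(vapply(spawn_seeds(cfg$seed, 12), function(s)
      run_simulation(cfg, seed = s)$eradicated, NA))
  }, 0)
  # monotone within Monte-Carlo tolerance, and the endpoints separate
  expect_true(all(diff(fracs) > -0.2))
  expect_lt(fracs[1], fracs[3])
  expect_equal(fracs[3], 1)
})

test_that("threshold search contracts hold", {
  expect_error(find_eradication_threshold(small_config(), numeric(0)),
               "non-empty")
  expect_error(find_eradication_threshold(small_config(), c(0.5, 0.4)),
               "ascending")
  expect_error(find_eradication_threshold(small_config(), c(0.5, 1),
                                          required_fraction = 0), "fraction")
  # grid {0, 1} at small scale: P_Y = 0 cannot eradicate, P_Y = 1 does
  cfg <- small_config(k = 200, inoculum = 20, years = 10, seed = 9)
  th <- find_eradication_threshold(cfg, c(0, 1), required_fraction = 1,
                                   replicates = 5)
  expect_equal(th$threshold, 1)
  expect_false(th$details$qualified[1])
})
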