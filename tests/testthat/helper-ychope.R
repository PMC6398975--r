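# Shared helpers for the test suite. Fixtures are built in code; no files.

# A small, fast configuration used where full scale is not the point.
small_config <- function(k = 200, inoculum = 4, years = 2, f_max = 1,
                         p_y = 1, p_n = 0, placement = "noncoding",
                         p_nf = 1, seed = 1, strategy = "ychope",
                         xshredder = NULL) {
  sim_config(
    drive = drive_params(p_y = p_y, p_n = p_n, p_nf = p_nf,
                         placement = placement),
    demog = demog_params(k = k, f_max = f_max),
    strategy = strategy, xshredder = xshredder,
    inoculum_size = inoculum, years = years, replicates = 1, seed = seed)
}

# Independent brute-force oracle for the homing transition distribution:
# enumerates cut patterns via expand.grid (a deliberately different
# implementation from build_homing_table's bitmask loop) and returns
# P(homing) and the distribution over remaining-site counts j.
oracle_homing <- function(s, p_c, p_n) {
  pats <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), s)))
  p_hom <- 0
  pj <- setNames(numeric(s + 1), 0:s)  # includes the no-cut j = s mass
  for (r in seq_len(nrow(pats))) {
    cut <- pats[r, ]
    pr <- prod(ifelse(cut, p_c, 1 - p_c))
    nc <- sum(cut)
    if (nc == 0) {
      pj["" %+% s] <- pj["" %+% s] + pr
    } else {
      p_hom <- p_hom + pr * (1 - p_n)
      idx <- which(cut)
      span <- min(idx):max(idx)
      j <- sum(!cut[setdiff(seq_len(s), span)])
      pj["" %+% j] <- pj["" %+% j] + pr * p_n
    }
  }
  list(homing = p_hom, pj = pj)
}

`%+%` <- function(a, b) paste0(a, b)

# allele frequency helpers over a trajectory data frame
g_allele_freq <- function(tr) {
  (tr$WG + 2 * tr$GG + tr$GR) / (2 * pmax(tr$N, 1))
}

r_allele_freq <- function(tr) {
  (tr$WR + 2 * tr$RR + tr$GR) / (2 * pmax(tr$N, 1))
}

expect_conserved <- function(tr) {
  expect_equal(tr$XX + tr$XY + tr$XO, tr$N)
  expect_equal(tr$WW + tr$WG + tr$GG + tr$WR + tr$GR + tr$RR, tr$N)
}
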