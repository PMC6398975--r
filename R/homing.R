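# Exact per-gamete homing transition distribution under simultaneous cutting.
#
# In a germline homing event on a wildtype allele with s susceptible sites,
# each site is cut independently with probability P_C. If no site is cut the
# allele is unchanged. If at least one site is cut, repair is homing
# (conversion to the drive) with probability 1 - P_N, or NHEJ with
# probability P_N. Under NHEJ every cut site is mutated (loses
# susceptibility); if two or more sites were cut, the sequence between the
# outermost cut sites is deleted, which also removes any uncut sites lying
# between them. The susceptible sites remaining afterwards are exactly the
# uncut sites outside the deleted span.

#' Exact homing transition table
#'
#' Enumerates all `2^s` cut subsets of a wildtype allele with `s` susceptible
#' sites and returns the exact distribution of per-gamete homing outcomes:
#' successful homing (conversion to the drive allele) versus each NHEJ/no-cut
#' outcome `(j, deletion, d)` with `j` susceptible sites remaining, a
#' deletion flag, and `d` new site mutations.
#'
#' The probability of successful homing is
#' \deqn{(1 - P_N)\,(1 - (1 - P_C)^s) = 1 - \sum_j P_{sj},}
#' where \eqn{P_{sj}} is the probability of moving from `s` to `j`
#' susceptible sites without acquiring the drive.
#'
#' @param s Current number of susceptible sites, `1 <= s <= params$n_guides`.
#' @param params A [drive_params()] object (`p_c`, `p_n`, `n_guides` used).
#' @return An object of class `homing_table`: a list with `s`,
#'   `homing_prob`, and `transitions`, a data frame with columns `j`,
#'   `deletion`, `d` (new mutations) and `prob`. `homing_prob +
#'   sum(transitions$prob)` is 1 to within 1e-12.
#' @examples
#' ht <- build_homing_table(3, drive_params(p_c = 0.95, p_n = 0.1))
#' ht$homing_prob + sum(ht$transitions$prob)  # 1
#' @export
build_homing_table <- function(s, params) {
  stopifnot(inherits(params, "drive_params"))
  if (!is.numeric(s) || length(s) != 1L || s != as.integer(s))
    stop("`s` must be a single integer", call. = FALSE)
  s <- as.integer(s)
  if (s < 1L || s > params$n_guides)
    stop(sprintf("`s` must be in [1, n_guides = %d]", params$n_guides),
         call. = FALSE)
  pc <- params$p_c
  pn <- params$p_n

  out <- list()  # keyed "j.del.d" -> prob
  add <- function(j, del, d, p) {
    key <- paste(j, as.integer(del), d, sep = ".")
    out[[key]] <<- (out[[key]] %||% 0) + p
  }

  homing_prob <- 0
  for (mask in 0:(2^s - 1L)) {
    cut <- which(bitwAnd(mask, bitwShiftL(1L, 0:(s - 1L))) != 0L)
    ncut <- length(cut)
    p_subset <- pc^ncut * (1 - pc)^(s - ncut)
    if (ncut == 0L) {
      add(s, FALSE, 0L, p_subset)           # no cut: unchanged
      next
    }
    homing_prob <- homing_prob + p_subset * (1 - pn)
    p_nhej <- p_subset * pn
    if (p_nhej > 0) {
      if (ncut == 1L) {
        add(s - 1L, FALSE, 1L, p_nhej)      # single indel, no deletion
      } else {
        span <- seq.int(min(cut), max(cut))
        j <- s - length(union(cut, span))   # uncut sites outside the span
        add(j, TRUE, ncut, p_nhej)
      }
    }
  }

  keys <- do.call(rbind, strsplit(names(out), ".", fixed = TRUE))
  transitions <- data.frame(
    j = as.integer(keys[, 1]),
    deletion = keys[, 2] == "1",
    d = as.integer(keys[, 3]),
    prob = unname(unlist(out))
  )
  transitions <- transitions[order(-transitions$j, transitions$d), ,
                             drop = FALSE]
  rownames(transitions) <- NULL
  structure(list(s = s, params = params, homing_prob = homing_prob,
                 transitions = transitions),
            class = "homing_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.homing_table <- function(x, ...) {
  cat(sprintf("<homing_table> s=%d homing_prob=%.6g\n", x$s, x$homing_prob))
  print(x$transitions)
  invisible(x)
}

# Allele-level outcome distribution for one homing event, as integer engine
# codes. Functionality under coding placement is resolved here: an NHEJ
# outcome with d new mutations is non-functional with probability
#   q = 1                      if a deletion occurred,
#   q = 1 - (1 - p_nf)^d       otherwise,
# and inheriting a non-functional allele is embryonic-lethal (code -2).
# Under non-coding placement functionality is ignored entirely.
# Code -1 denotes successful homing (the gamete allele becomes the drive).
homing_outcome_dist <- function(s, params) {
  ht <- build_homing_table(s, params)
  tr <- ht$transitions
  coding <- params$placement == "coding"
  codes <- integer(0); probs <- numeric(0)
  if (ht$homing_prob > 0) {
    codes <- -1L; probs <- ht$homing_prob
  }
  for (i in seq_len(nrow(tr))) {
    q <- if (!coding || tr$d[i] == 0L) 0
         else if (tr$deletion[i]) 1
         else 1 - (1 - params$p_nf)^tr$d[i]
    code_ok <- 1L + 2L * tr$j[i] + as.integer(tr$deletion[i])
    if (q < 1) { codes <- c(codes, code_ok); probs <- c(probs, tr$prob[i] * (1 - q)) }
    if (q > 0) { codes <- c(codes, -2L);     probs <- c(probs, tr$prob[i] * q) }
  }
  list(codes = codes, probs = probs, cum = cumsum(probs))
}

# One outcome table per possible site count s = 1..n_guides, for the engine.
make_transition_tables <- function(params) {
  lapply(seq_len(params$n_guides), function(s) homing_outcome_dist(s, params))
}
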