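# Global sensitivity analysis: Latin hypercube design over the ten model
# parameters, one simulation per sample, and a boosted-regression-tree
# emulator of the binary eradication outcome (relative influence, partial
# dependence, staged-CV tree selection, subsample convergence diagnostics).

#' Parameter ranges for the global sensitivity analysis
#'
#' The ten parameters and their sampling distributions: continuous uniforms
#' except `n_guides` and `f_max`, which are discrete uniform over their
#' integer support.
#'
#' @return A data frame with columns `name`, `dist` (`"uniform"` or
#'   `"discrete"`), `lo`, `hi`.
#' @export
sensitivity_ranges <- function() {
  data.frame(
    name = c("p_c", "p_n", "n_guides", "p_nf", "p_y", "xo_fertility",
             "p_x_xo", "f_max", "litter_mean", "r_max"),
    dist = c("uniform", "uniform", "discrete", "uniform", "uniform",
             "uniform", "uniform", "discrete", "uniform", "uniform"),
    lo = c(0.7, 0, 1, 0.66, 0.5, 0, 0.5, 1, 2, 6),
    hi = c(1, 0.5, 5, 1, 1, 1, 1, 10, 10, 9)
  )
}

#' Latin hypercube sample
#'
#' Stratified space-filling design: for every continuous parameter the `n`
#' samples fall exactly one per equal-probability stratum (with uniform
#' within-stratum jitter and an independent random pairing across
#' parameters); discrete parameters are sampled uniformly over their
#' integer support.
#'
#' @param ranges A data frame as returned by [sensitivity_ranges()].
#' @param n Number of samples (>= 2).
#' @param seed Seed making the design reproducible.
#' @return An object of class `lhs_design`: a data frame of `n` rows with
#'   one column per parameter, with the ranges and seed as attributes.
#' @export
lhs_sample <- function(ranges = sensitivity_ranges(), n, seed = 1) {
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  if (!all(c("name", "dist", "lo", "hi") %in% names(ranges)) ||
      any(ranges$lo >= ranges$hi))
    stop("invalid `ranges`", call. = FALSE)
  set.seed(seed)
  cols <- lapply(seq_len(nrow(ranges)), function(i) {
    lo <- ranges$lo[i]; hi <- ranges$hi[i]
    if (ranges$dist[i] == "discrete") {
      sample(seq.int(lo, hi), n, replace = TRUE)
    } else {
      u <- (sample.int(n) - runif(n)) / n   # one point per stratum
      lo + u * (hi - lo)
    }
  })
  design <- as.data.frame(setNames(cols, ranges$name))
  attr(design, "ranges") <- ranges
  attr(design, "seed") <- seed
  class(design) <- c("lhs_design", "data.frame")
  design
}

#' Run the simulation once per design row
#'
#' Substitutes each row of the design into the base configuration (coding
#' placement for the drive) and runs a single replicate per row; the outcome
#' is the binary eradication indicator. Per-row seeds derive from
#' `base_config$seed`, so a duplicated row with the same position is
#' reproducible via its seed.
#'
#' @param design An [lhs_sample()] design (columns named as in
#'   [sensitivity_ranges()]).
#' @param base_config A [sim_config()]; defaults to the scaled-down desk
#'   setting K = 1000 with a 1% inoculum.
#' @param progress Print a progress line every `progress` rows (0 = quiet).
#' @return Integer vector of 0/1 eradication outcomes, one per row.
#' @export
run_design <- function(design,
                       base_config = sim_config(
                         drive = drive_params(placement = "coding"),
                         demog = demog_params(k = 1000),
                         inoculum_size = 10, replicates = 1),
                       progress = 0) {
  seeds <- spawn_seeds(base_config$seed, nrow(design))
  out <- integer(nrow(design))
  for (i in seq_len(nrow(design))) {
    cfg <- base_config
    row <- design[i, , drop = FALSE]
    for (nm in c("p_c", "p_n", "p_nf", "p_y", "xo_fertility", "p_x_xo"))
      if (!is.null(row[[nm]])) cfg$drive[[nm]] <- row[[nm]]
    if (!is.null(row$n_guides)) cfg$drive$n_guides <- as.integer(row$n_guides)
    for (nm in c("litter_mean", "r_max"))
      if (!is.null(row[[nm]])) cfg$demog[[nm]] <- row[[nm]]
    if (!is.null(row$f_max)) cfg$demog$f_max <- as.integer(row$f_max)
    cfg$drive$placement <- "coding"
    res <- run_simulation(cfg, seed = seeds[i])
    out[i] <- as.integer(res$eradicated)
    if (progress > 0 && i %% progress == 0)
      message(sprintf("run_design: %d/%d (erad so far %.3f)", i,
                      nrow(design), mean(out[seq_len(i)])))
  }
  out
}

#' Fit the boosted-regression-tree emulator
#'
#' Gradient-boosted classification trees with Bernoulli deviance and logit
#' link: tree complexity (number of splits per tree) 5, learning rate 0.01
#' and bag fraction 0.75 by default. The number of trees is chosen by staged
#' k-fold cross-validation (trees are added in steps and fitting stops when
#' the pooled held-out deviance has stopped improving); the final model is
#' refit on all data with the chosen tree count. Relative influence is the
#' split-gain (loss-reduction) total attributable to each parameter,
#' normalized to percent.
#'
#' @param design Design data frame (numeric columns; discrete parameters
#'   enter as ordinal numeric features).
#' @param outcomes Binary 0/1 outcome vector, one per design row.
#' @param n_splits Tree complexity (splits per tree).
#' @param shrinkage Learning rate.
#' @param bag_fraction Stochastic subsample fraction per tree.
#' @param n_folds CV folds for the staged tree-count selection.
#' @param max_trees,cv_step,patience Staged-fitting controls.
#' @param min_node Minimum observations per terminal node.
#' @param seed Seed for bagging and fold assignment.
#' @return An object of class `brt_emulator`: relative influence (percent,
#'   summing to 100), the fitted model, chosen tree count, CV deviance
#'   curve, held-out AUC and deviance at the chosen count, and the settings.
#' @export
fit_emulator <- function(design, outcomes, n_splits = 5, shrinkage = 0.01,
                         bag_fraction = 0.75, n_folds = 10,
                         max_trees = 3000, cv_step = 50, patience = 200,
                         min_node = 10, seed = 1) {
  X <- as.matrix(as.data.frame(design))
  storage.mode(X) <- "double"
  y <- as.numeric(outcomes)
  if (length(y) != nrow(X))
    stop("`outcomes` must have one value per design row", call. = FALSE)
  if (!all(y %in% c(0, 1)))
    stop("`outcomes` must be binary 0/1", call. = FALSE)
  if (all(y == 0) || all(y == 1))
    stop("degenerate outcomes (all 0 or all 1): influences are undefined",
         call. = FALSE)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(n_folds) - 1L, nrow(X)))
  cv <- cpp_gbm_cv(X, y, fold_id, max_trees, cv_step, patience, n_splits,
                   shrinkage, bag_fraction, min_node)
  model <- cpp_gbm_fit(X, y, cv$n_trees, n_splits, shrinkage, bag_fraction,
                       min_node)
  imp <- model$importance
  influence <- if (sum(imp) > 0) 100 * imp / sum(imp)
               else rep(100 / ncol(X), ncol(X))
  names(influence) <- colnames(X)
  heldout_p <- plogis(cv$heldout_link)
  structure(list(
    influence = influence,
    model = model,
    n_trees = cv$n_trees,
    cv_deviance = cv$cv_deviance,
    cv_curve = data.frame(n_trees = cv$counts, deviance = cv$curve),
    cv_auc = auc(y, heldout_p),
    settings = list(n_splits = n_splits, shrinkage = shrinkage,
                    bag_fraction = bag_fraction, n_folds = n_folds,
                    min_node = min_node),
    feature_names = colnames(X),
    design = as.data.frame(design)
  ), class = "brt_emulator")
}

auc <- function(y, p) {
  r <- rank(p)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.brt_emulator <- function(x, ...) {
  cat(sprintf("<brt_emulator> %d trees (CV deviance %.4f, AUC %.3f)\n",
              x$n_trees, x$cv_deviance, x$cv_auc))
  cat("relative influence (%):\n")
  print(round(sort(x$influence, decreasing = TRUE), 2))
  invisible(x)
}

#' Predict eradication probability from the emulator
#'
#' @param object A `brt_emulator`.
#' @param newdata Data frame with the design columns.
#' @param ... Unused.
#' @return Predicted probabilities.
#' @export
predict.brt_emulator <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  storage.mode(X) <- "double"
  plogis(cpp_gbm_predict_link(object$model, X, -1L))
}

# Conditioning values for the less influential parameters used by the
# shipped partial-dependence defaults.
pd_default_fixed <- function() {
  list(litter_mean = 6, xo_fertility = 0.6, p_n = 0.1, r_max = 7.76,
       p_nf = 0.66, n_guides = 3, p_x_xo = 0.66, p_c = 0.95)
}

#' Partial-dependence curves from the emulator
#'
#' Evaluates the predicted eradication probability over a grid of one or
#' more focal parameters, with non-focal parameters either clamped at fixed
#' values (`mode = "conditional"`, the default, using [pd_default_fixed()]
#' where not supplied) or marginalized over the design
#' (`mode = "marginal"`).
#'
#' @param emulator A fitted `brt_emulator`.
#' @param focal_params Character vector of focal parameter names.
#' @param fixed_values Named list of clamp values for non-focal parameters
#'   (conditional mode); defaults from [pd_default_fixed()], remaining
#'   parameters at their design medians.
#' @param grid_n Grid points per focal parameter (discrete parameters use
#'   their full integer support).
#' @param mode `"conditional"` or `"marginal"`.
#' @return A data frame: one column per focal parameter plus `prob`.
#' @export
partial_dependence <- function(emulator, focal_params,
                               fixed_values = NULL, grid_n = 25,
                               mode = c("conditional", "marginal")) {
  mode <- match.arg(mode)
  nms <- emulator$feature_names
  bad <- setdiff(focal_params, nms)
  if (length(bad))
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  ranges <- sensitivity_ranges()
  grid1 <- function(nm) {
    r <- ranges[ranges$name == nm, ]
    if (nrow(r) == 1 && r$dist == "discrete") seq.int(r$lo, r$hi)
    else if (nrow(r) == 1) seq(r$lo, r$hi, length.out = grid_n)
    else seq(min(emulator$design[[nm]]), max(emulator$design[[nm]]),
             length.out = grid_n)
  }
  grid <- expand.grid(lapply(setNames(nm = focal_params), grid1))
  others <- setdiff(nms, focal_params)
  if (mode == "conditional") {
    fixed <- pd_default_fixed()
    for (nm in names(fixed_values %||% list())) fixed[[nm]] <- fixed_values[[nm]]
    newdata <- grid
    for (nm in others)
      newdata[[nm]] <- fixed[[nm]] %||% stats::median(emulator$design[[nm]])
    grid$prob <- predict(emulator, newdata)
  } else {
    bg <- emulator$design[, others, drop = FALSE]
    grid$prob <- vapply(seq_len(nrow(grid)), function(i) {
      newdata <- bg
      for (nm in focal_params) newdata[[nm]] <- grid[[nm]][i]
      mean(predict(emulator, newdata))
    }, 0)
  }
  grid
}

#' Emulator convergence diagnostics over nested subsamples
#'
#' Refits the emulator on nested subsamples of increasing size and reports
#' the relative-influence vector and CV performance per size; flags
#' non-convergence when the influence vectors of the two largest sizes
#' differ by more than `tol` (maximum absolute difference, percentage
#' points).
#'
#' @param design,outcomes As for [fit_emulator()].
#' @param subsample_sizes Ascending vector (length >= 2) of subsample sizes.
#' @param tol Convergence tolerance in influence percentage points.
#' @param ... Passed to [fit_emulator()].
#' @return A list with `table` (size, CV deviance, CV AUC, one influence
#'   column per parameter), `converged`, and `max_abs_diff`.
#' @export
convergence_check <- function(design, outcomes, subsample_sizes, tol = 10,
                              ...) {
  if (length(subsample_sizes) < 2L)
    stop("`subsample_sizes` must have length >= 2", call. = FALSE)
  if (is.unsorted(subsample_sizes))
    stop("`subsample_sizes` must be ascending", call. = FALSE)
  if (max(subsample_sizes) > nrow(design))
    stop("subsample size exceeds design size", call. = FALSE)
  fits <- lapply(subsample_sizes, function(sz) {
    idx <- seq_len(sz)
    fit_emulator(design[idx, , drop = FALSE], outcomes[idx], ...)
  })
  infl <- do.call(rbind, lapply(fits, function(f) f$influence))
  tab <- data.frame(
    size = subsample_sizes,
    cv_deviance = vapply(fits, function(f) f$cv_deviance, 0),
    cv_auc = vapply(fits, function(f) f$cv_auc, 0),
    infl
  )
  k <- length(fits)
  d <- max(abs(infl[k, ] - infl[k - 1L, ]))
  list(table = tab, converged = d <= tol, max_abs_diff = d)
}
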