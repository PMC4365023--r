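# Shared fixtures: all synthetic, built in code at test time.

# the full 48 h OmniLog-style grid (192 points at 0.25 h)
grid_full <- function() seq(0, 47.75, by = 0.25)

# coarser 0.5 h grid used where the full grid adds nothing but runtime
grid_coarse <- function() seq(0, 47.5, by = 0.5)

# Separable 96-well plate: 40 logistic wells (asym 250, xmid 12, scale 2)
# and 56 flat wells at level 30, Gaussian noise sd 5, truncated at 0.
# Active wells come first (A01..D04).
separable_plate <- function(seed = 11, noise_sd = 5, times = grid_full()) {
  set.seed(seed)
  active_curve <- logistic_curve(times, 250, 12, 2)
  sig <- rbind(
    t(replicate(40, active_curve + rnorm(length(times), 0, noise_sd))),
    t(replicate(56, 30 + rnorm(length(times), 0, noise_sd)))
  )
  rownames(sig) <- well_ids()
  list(
    plate = pm_plate("sep1", times, pmax(sig, 0)),
    truth = setNames(rep(c("active", "non-active"), c(40, 56)), well_ids())
  )
}

# Three noise-free replicate plates equal to a common plate scaled by
# `scales`; half the wells logistic, half flat.
scaled_replicates <- function(scales = c(1.25, 1.0, 0.8),
                              times = grid_coarse(), n_each = 10) {
  asyms <- seq(150, 290, length.out = n_each)
  levels <- seq(10, 40, length.out = n_each)
  base <- rbind(
    t(sapply(asyms, function(a) logistic_curve(times, a, 12, 2))),
    t(sapply(levels, function(l) rep(l, length(times))))
  )
  rownames(base) <- well_ids()[seq_len(2 * n_each)]
  plates <- lapply(seq_along(scales), function(r) {
    pm_plate(as.character(r), times, base * scales[r],
             factor_a = "28", factor_b = "s1", replicate = r)
  })
  list(experiment = pm_experiment(plates, c("28", "s1")), base = base)
}

# Balanced 2x2 design with n_rep arrays per cell, control = (1,1).
design_2x2 <- function(n_rep = 3) {
  structure(
    list(
      a = rep(c(1, 2, 1, 2), each = n_rep),
      b = rep(c(1, 1, 2, 2), each = n_rep),
      levels_a = c("A1", "A2"), levels_b = c("B1", "B2"),
      array_id = as.character(seq_len(4 * n_rep))
    ),
    class = "pm_design"
  )
}

# Exact Gaussian posterior for the 2x2 effects model with flat prior on
# the control level and N(0, v0) priors on the effects: the independent
# oracle for the Gibbs sampler.
conjugate_posterior <- function(y_col, design, sigma2, v0 = 1e6) {
  X <- cbind(1, design$a == 2, design$b == 2,
             design$a == 2 & design$b == 2) * 1
  V0inv <- diag(c(0, 1 / v0, 1 / v0, 1 / v0))
  S <- solve(t(X) %*% X / sigma2 + V0inv)
  m <- S %*% (t(X) %*% y_col / sigma2)
  list(mean = drop(m), sd = sqrt(diag(S)))
}

# Batch-means Monte-Carlo standard error of a chain's mean.
mc_se <- function(x, n_batches = 40) {
  n <- length(x)
  bs <- floor(n / n_batches)
  bm <- colMeans(matrix(x[seq_len(bs * n_batches)], nrow = bs))
  sd(bm) / sqrt(n_batches)
}

# Minimal chains object for summary-level tests (point-mass or given
# draws), shaped like sample_effects() output.
fake_chains <- function(draws_list, tstar, types = NULL) {
  nms <- names(draws_list)
  if (is.null(types)) {
    types <- ifelse(nms == "zeta", "control", "A")
  }
  structure(
    list(
      substrate = "fake",
      draws = draws_list,
      effects = data.frame(
        name = nms, type = types,
        level_a = "A2", level_b = "B1", stringsAsFactors = FALSE
      ),
      tstar = tstar
    ),
    class = "pm_effect_chains"
  )
}
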