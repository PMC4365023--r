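#' Simulate a factorial PM experiment with known ground truth
#'
#' Generates a complete plate-level experiment in the shape of a typical
#' small PM study: a 2 x 2 factorial design (e.g. temperature x strain)
#' with 3 replicate arrays per condition, 96 wells read every 0.25 h for
#' 48 h. Active wells follow the logistic model, non-active wells a
#' near-flat line; each array's signals are scaled by a multiplicative
#' array effect, Gaussian measurement noise is added, and negative
#' values are truncated at zero. The default per-condition active
#' fractions (0.44, 0.44, 0.33, 0.22) echo the activity rates typically
#' seen when temperature stress suppresses metabolism in one strain more
#' than the other.
#'
#' Activity status and well-level curve parameters are drawn once per
#' condition and shared across its replicates, so replicates differ only
#' by their array effect and noise — the situation the normalization
#' stage is designed for. Condition effects, when given, shift the
#' logistic asymptote of selected wells in the non-control conditions;
#' those wells are forced active everywhere so the shift is observable.
#'
#' @param n_wells number of wells per plate (default 96).
#' @param times time grid in hours (default 0 to 47.75 by 0.25).
#' @param factor_a_levels,factor_b_levels condition labels; the first of
#'   each is the control level.
#' @param n_replicates replicate arrays per condition.
#' @param active_fraction matrix (levels_a x levels_b) of per-condition
#'   active probabilities, or a single number.
#' @param asym_range,xmid_range,scale_range uniform ranges of the
#'   logistic parameters of active wells.
#' @param nonactive_level_range,nonactive_slope_range uniform ranges of
#'   the line parameters of non-active wells.
#' @param noise_sd measurement noise standard deviation (signal units).
#' @param array_factors named numeric vector of multiplicative array
#'   effects (names = array ids), or `NULL` to draw them uniformly from
#'   `array_factor_range`.
#' @param array_factor_range range of random array effects.
#' @param effects optional list `list(wells =, alpha =, beta =, gamma =)`:
#'   additive shifts of the logistic asymptote for the listed wells in
#'   the off-control conditions (alpha when factor A is off-control,
#'   beta when factor B is, gamma when both are).
#' @param seed master seed; each plate's noise uses its own stream
#'   derived from it, so adding plates does not perturb existing ones.
#' @return list with `experiment` (a [pm_experiment()]) and `truth`
#'   (labels per condition, per-array factors, per-well parameters and
#'   the injected effects).
#' @export
simulate_experiment <- function(n_wells = 96,
                                times = seq(0, 47.75, by = 0.25),
                                factor_a_levels = c("28", "37"),
                                factor_b_levels = c("53/03", "8081c"),
                                n_replicates = 3,
                                active_fraction = matrix(
                                  c(0.44, 0.44, 0.33, 0.22),
                                  nrow = 2, byrow = TRUE
                                ),
                                asym_range = c(150, 300),
                                xmid_range = c(8, 16),
                                scale_range = c(1.5, 3),
                                nonactive_level_range = c(10, 50),
                                nonactive_slope_range = c(0, 0.3),
                                noise_sd = 5,
                                array_factors = NULL,
                                array_factor_range = c(0.85, 1.15),
                                effects = NULL,
                                seed = 1) {
  La <- length(factor_a_levels); Lb <- length(factor_b_levels)
  if (length(active_fraction) == 1) {
    active_fraction <- matrix(active_fraction, La, Lb)
  }
  stopifnot(nrow(active_fraction) == La, ncol(active_fraction) == Lb,
            all(active_fraction >= 0 & active_fraction <= 1),
            noise_sd >= 0, n_replicates >= 1)
  wells <- if (n_wells == 96) well_ids() else
    well_ids(ceiling(n_wells / 12), 12)[seq_len(n_wells)]

  set.seed(seed)
  n_arrays <- La * Lb * n_replicates
  array_ids <- as.character(seq_len(n_arrays))
  if (is.null(array_factors)) {
    array_factors <- stats::setNames(
      stats::runif(n_arrays, array_factor_range[1], array_factor_range[2]),
      array_ids
    )
  } else {
    array_factors <- array_factors[array_ids]
    stopifnot(!anyNA(array_factors), all(array_factors > 0))
  }

  well_params <- data.frame(
    well = wells,
    asym = stats::runif(n_wells, asym_range[1], asym_range[2]),
    xmid = stats::runif(n_wells, xmid_range[1], xmid_range[2]),
    scale = stats::runif(n_wells, scale_range[1], scale_range[2]),
    na_level = stats::runif(n_wells, nonactive_level_range[1],
                            nonactive_level_range[2]),
    na_slope = stats::runif(n_wells, nonactive_slope_range[1],
                            nonactive_slope_range[2]),
    stringsAsFactors = FALSE
  )

  eff_wells <- if (is.null(effects)) character(0) else effects$wells
  eshift <- function(aa, bb) {
    if (is.null(effects)) return(0)
    (if (aa > 1) effects$alpha %||% 0 else 0) +
      (if (bb > 1) effects$beta %||% 0 else 0) +
      (if (aa > 1 && bb > 1) effects$gamma %||% 0 else 0)
  }

  # per-condition activity labels, shared across replicates
  labels <- list()
  for (aa in seq_len(La)) for (bb in seq_len(Lb)) {
    lab <- ifelse(stats::runif(n_wells) < active_fraction[aa, bb],
                  "active", "non-active")
    lab[wells %in% eff_wells] <- "active"
    labels[[paste(factor_a_levels[aa], factor_b_levels[bb], sep = "|")]] <-
      stats::setNames(lab, wells)
  }

  plates <- list()
  idx <- 0
  for (aa in seq_len(La)) for (bb in seq_len(Lb)) {
    key <- paste(factor_a_levels[aa], factor_b_levels[bb], sep = "|")
    lab <- labels[[key]]
    clean <- matrix(0, n_wells, length(times),
                    dimnames = list(wells, NULL))
    for (w in seq_len(n_wells)) {
      p <- well_params[w, ]
      clean[w, ] <- if (lab[w] == "active") {
        asym <- p$asym +
          if (wells[w] %in% eff_wells) eshift(aa, bb) else 0
        logistic_curve(times, max(asym, 1), p$xmid, p$scale)
      } else {
        p$na_level + p$na_slope * times
      }
    }
    for (r in seq_len(n_replicates)) {
      idx <- idx + 1
      id <- array_ids[idx]
      # independent noise stream per plate
      set.seed((seed + 7919L * idx) %% .Machine$integer.max)
      noise <- matrix(stats::rnorm(length(clean), 0, noise_sd),
                      n_wells, length(times))
      sig <- pmax(array_factors[[id]] * clean + noise, 0)
      rownames(sig) <- wells
      plates[[id]] <- pm_plate(id, times, sig,
                               factor_a = factor_a_levels[aa],
                               factor_b = factor_b_levels[bb],
                               replicate = r)
    }
  }

  experiment <- pm_experiment(
    plates, control = c(factor_a_levels[1], factor_b_levels[1])
  )
  list(
    experiment = experiment,
    truth = list(
      labels = labels, array_factors = array_factors,
      well_params = well_params, effects = effects, seed = seed
    )
  )
}

#' Simulate data straight from the effects-model likelihood
#'
#' Draws a per-substrate data matrix `y` directly from the hierarchical
#' two-factor model with known parameters — the direct test harness for
#' [sample_effects()], bypassing the plate-level stages.
#'
#' @param design a [pm_design()].
#' @param zeta control level: scalar or vector over `tstar`.
#' @param alpha,beta,gamma effect sizes for the off-control levels:
#'   scalars (applied to every off-control level) or vectors over
#'   `tstar`.
#' @param sigma2 observation noise variance.
#' @param tstar time points.
#' @param seed seed.
#' @return list with `input` (usable by [sample_effects()]) and `truth`
#'   (the generating parameter values, one row per effect of the
#'   design, matching the sampler's `effects` table).
#' @export
simulate_effect_dataset <- function(design, zeta = 150, alpha = 0, beta = 0,
                                    gamma = 0, sigma2 = 100,
                                    tstar = c(0, 12, 24, 36, 47.75),
                                    seed = 1) {
  N <- length(design$a); Tt <- length(tstar)
  as_row <- function(x) {
    if (length(x) == 1) rep(x, Tt) else {
      stopifnot(length(x) == Tt); x
    }
  }
  zeta <- as_row(zeta); alpha <- as_row(alpha)
  beta <- as_row(beta); gamma <- as_row(gamma)
  set.seed(seed)
  mu <- matrix(zeta, N, Tt, byrow = TRUE)
  offa <- design$a > 1; offb <- design$b > 1
  mu[offa, ] <- mu[offa, , drop = FALSE] +
    matrix(alpha, sum(offa), Tt, byrow = TRUE)
  mu[offb, ] <- mu[offb, , drop = FALSE] +
    matrix(beta, sum(offb), Tt, byrow = TRUE)
  both <- offa & offb
  mu[both, ] <- mu[both, , drop = FALSE] +
    matrix(gamma, sum(both), Tt, byrow = TRUE)
  y <- mu + matrix(stats::rnorm(N * Tt, 0, sqrt(sigma2)), N, Tt)
  rownames(y) <- design$array_id
  list(
    input = list(substrate = "simulated", y = y, tstar = tstar,
                 array_id = design$array_id),
    truth = list(zeta = zeta, alpha = alpha, beta = beta, gamma = gamma,
                 mu = mu, sigma2 = sigma2)
  )
}

#' Write a simulated experiment to disk
#'
#' Emits one wide CSV per plate, a metadata CSV and a ground-truth
#' labels CSV, in the formats read back by [read_experiment()].
#'
#' @param sim result of [simulate_experiment()].
#' @param dir output directory (created if needed).
#' @return path of the metadata file, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- sim$experiment$meta
  meta$file <- paste0("plate_", meta$array_id, ".csv")
  for (i in seq_len(nrow(meta))) {
    write_plate(sim$experiment$plates[[meta$array_id[i]]],
                file.path(dir, meta$file[i]))
  }
  utils::write.csv(meta, file.path(dir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  truth <- do.call(rbind, lapply(names(sim$truth$labels), function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    data.frame(factor_a = parts[1], factor_b = parts[2],
               well = names(sim$truth$labels[[k]]),
               label = unname(sim$truth$labels[[k]]),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(truth, file.path(dir, "truth_labels.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(file.path(dir, "metadata.csv"))
}
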