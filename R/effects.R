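#' Thin a time grid for effect identification
#'
#' The variance analysis runs on a subset of time points T* of the full
#' grid to keep the computation light. Either a `stride` (every k-th
#' point, always keeping the first and the last) or an explicit `subset`
#' of times already on the grid may be given. The default stride of 16
#' corresponds to one point every 4 h on a 0.25 h grid.
#'
#' @param times full time grid (hours).
#' @param stride keep every `stride`-th point (default 16).
#' @param subset explicit times to keep; must all lie on the grid.
#' @return ordered numeric vector T*.
#' @export
thin_timepoints <- function(times, stride = 16, subset = NULL) {
  if (!is.null(subset)) {
    idx <- match(round(subset, 10), round(times, 10))
    if (anyNA(idx)) {
      stop("requested time(s) not on the grid: ",
           paste(subset[is.na(idx)], collapse = ", "))
    }
    return(times[sort(unique(idx))])
  }
  stopifnot(stride >= 1)
  idx <- unique(c(seq(1, length(times), by = stride), length(times)))
  times[idx]
}

#' Build a factorial design from an experiment
#'
#' Maps every plate to integer factor levels, with the control condition
#' at `(a = 1, b = 1)`; effect parameters are defined relative to this
#' control.
#'
#' @param experiment a [pm_experiment()].
#' @return an object of class `pm_design`: list with `a`, `b` (integer
#'   level per array, in plate order), `levels_a`, `levels_b` (level
#'   labels, control first) and `array_id`.
#' @export
pm_design <- function(experiment) {
  m <- experiment$meta
  ctrl <- experiment$control
  levels_a <- c(ctrl[1], setdiff(unique(m$factor_a), ctrl[1]))
  levels_b <- c(ctrl[2], setdiff(unique(m$factor_b), ctrl[2]))
  structure(
    list(
      a = match(m$factor_a, levels_a),
      b = match(m$factor_b, levels_b),
      levels_a = levels_a, levels_b = levels_b,
      array_id = m$array_id
    ),
    class = "pm_design"
  )
}

#' Assemble the per-substrate input of the variance analysis
#'
#' For one well (substrate), each array's profile is denoised by fitting
#' the model matching its activity label (logistic for active with
#' linear fallback, line for non-active) and the fitted values are
#' evaluated at the thinned time points T*, truncated at zero. These
#' fitted values — not the raw signals — are the data of the Bayesian
#' model.
#'
#' @param experiment a [pm_experiment()] (normally the normalized one).
#' @param labels named list array id -> label vector (e.g. the `labels`
#'   element of a [normalize_experiment()] result).
#' @param well well id, e.g. `"B08"`.
#' @param tstar thinned time points (see [thin_timepoints()]).
#' @return list with `substrate`, `y` (arrays x T* matrix of fitted
#'   values), `tstar` and `array_id`.
#' @export
build_effect_input <- function(experiment, labels, well, tstar) {
  ids <- names(experiment$plates)
  y <- t(vapply(ids, function(j) {
    p <- experiment$plates[[j]]
    if (!well %in% p$wells) stop("well '", well, "' missing on array ", j)
    lab <- labels[[j]][well]
    fit <- fit_profile(p$times, p$signals[well, ], lab, eval_times = tstar)
    fit$fitted
  }, numeric(length(tstar))))
  rownames(y) <- ids
  colnames(y) <- format(tstar, trim = TRUE)
  list(substrate = well, y = y, tstar = tstar, array_id = ids)
}

#' Gibbs sampler for the hierarchical two-factor model
#'
#' For each time point t in T* (independently) the model is
#' \deqn{y_{i,t} \sim N(\mu_{i,t}, \sigma^2)}
#' with \eqn{\mu_{i,t} = \zeta_t} for the control arrays and
#' \eqn{\zeta_t + \alpha_{a_i,t} + \beta_{b_i,t} + \gamma_{a_i,b_i,t}}
#' otherwise (main effects enter whenever their factor is off-control,
#' the interaction only when both are). Priors are uninformative:
#' \eqn{\zeta_t \sim U(0, 400)} and zero-centred normal priors on
#' \eqn{\alpha, \beta, \gamma} whose default variance (1e6) is
#' effectively flat at metabolic-signal scales — effects of the
#' magnitude this analysis targets (tens to hundreds of signal units)
#' are not shrunk; see `effect_prior_var` to tighten it. The model
#' error \eqn{\sigma^2} is fixed at the user's value — it is the
#' sensitivity knob of the analysis — or estimated when
#' `sigma2 = "estimate"` under an Inverse-Gamma(0.001, 0.001) prior.
#'
#' All full conditionals are normal (truncated normal for \eqn{\zeta}),
#' so a single-site Gibbs sampler is exact; updates for different time
#' points are independent and performed in lockstep for speed.
#'
#' @param input result of [build_effect_input()], or any list with a
#'   numeric matrix `y` (arrays x time points) and `tstar`.
#' @param design a [pm_design()] covering the rows of `y`.
#' @param sigma2 model error variance (signal units squared), or
#'   `"estimate"`.
#' @param n_iter iterations per chain (including burn-in).
#' @param burn_in discarded initial iterations per chain.
#' @param n_chains number of independent chains.
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @param zeta_support prior support of the control level, default
#'   `c(0, 400)`.
#' @param effect_prior_var prior variance of alpha, beta, gamma.
#' @return an object of class `pm_effect_chains`: list with `draws` (a
#'   named list; each element a draws x time matrix of posterior
#'   samples), `effects` (data frame describing each element: type,
#'   level_a, level_b), `tstar`, `sigma2_draws` (when estimated) and the
#'   sampler settings.
#' @export
sample_effects <- function(input, design, sigma2 = 100,
                           n_iter = 5000, burn_in = 1000, n_chains = 2,
                           seed = 1, zeta_support = c(0, 400),
                           effect_prior_var = 1e6) {
  y <- input$y
  stopifnot(is.matrix(y), nrow(y) == length(design$a),
            burn_in < n_iter, n_chains >= 1)
  estimate_sigma <- identical(sigma2, "estimate")
  if (!estimate_sigma) stopifnot(is.numeric(sigma2), sigma2 > 0)
  N <- nrow(y); Tt <- ncol(y)
  La <- length(design$levels_a); Lb <- length(design$levels_b)
  a <- design$a; b <- design$b
  cell <- (a - 1) * Lb + b  # 1-based cell index for the gamma lookup

  # parameter bookkeeping: zeta, alpha_a (a != 1), beta_b (b != 1),
  # gamma_ab (a, b != 1)
  eff <- data.frame(
    name = "zeta", type = "control",
    level_a = design$levels_a[1], level_b = design$levels_b[1],
    stringsAsFactors = FALSE
  )
  for (aa in seq_len(La)[-1]) {
    eff <- rbind(eff, data.frame(
      name = paste0("alpha", aa), type = "A",
      level_a = design$levels_a[aa], level_b = design$levels_b[1]
    ))
  }
  for (bb in seq_len(Lb)[-1]) {
    eff <- rbind(eff, data.frame(
      name = paste0("beta", bb), type = "B",
      level_a = design$levels_a[1], level_b = design$levels_b[bb]
    ))
  }
  for (aa in seq_len(La)[-1]) for (bb in seq_len(Lb)[-1]) {
    eff <- rbind(eff, data.frame(
      name = paste0("gamma", aa, "_", bb), type = "interaction",
      level_a = design$levels_a[aa], level_b = design$levels_b[bb]
    ))
  }

  rows_a <- lapply(seq_len(La), function(aa) which(a == aa))
  rows_b <- lapply(seq_len(Lb), function(bb) which(b == bb))
  rows_g <- lapply(seq_len(La * Lb), function(cc) {
    aa <- (cc - 1) %/% Lb + 1; bb <- (cc - 1) %% Lb + 1
    if (aa == 1 || bb == 1) integer(0) else which(cell == cc)
  })
  noncontrol_cells <- which(rep(seq_len(La), each = Lb) != 1 &
                              rep(seq_len(Lb), times = La) != 1)
  empty <- c(
    vapply(seq_len(La)[-1], function(aa) length(rows_a[[aa]]) == 0, logical(1)),
    vapply(seq_len(Lb)[-1], function(bb) length(rows_b[[bb]]) == 0, logical(1)),
    lengths(rows_g[noncontrol_cells]) == 0
  )
  if (any(empty)) {
    warning("some non-control factor levels have no arrays; ",
            "their effects remain at the prior")
  }

  lo <- zeta_support[1]; hi <- zeta_support[2]
  v0 <- effect_prior_var
  keep <- n_iter - burn_in
  draws <- lapply(stats::setNames(eff$name, eff$name),
                  function(nm) matrix(NA_real_, keep * n_chains, Tt))
  sigma2_draws <- if (estimate_sigma) numeric(keep * n_chains) else NULL
  bound_warned <- FALSE

  rtruncnorm_vec <- function(mean, sd, lo, hi) {
    plo <- stats::pnorm(lo, mean, sd)
    phi <- stats::pnorm(hi, mean, sd)
    u <- plo + stats::runif(length(mean)) * (phi - plo)
    out <- stats::qnorm(pmin(pmax(u, 1e-15), 1 - 1e-15), mean, sd)
    pmin(pmax(out, lo), hi)
  }

  for (ch in seq_len(n_chains)) {
    set.seed(seed + ch - 1)
    s2 <- if (estimate_sigma) stats::var(as.vector(y)) + 1e-8 else sigma2
    # initialize at rough data-driven values
    ctrl_rows <- intersect(rows_a[[1]], rows_b[[1]])
    zeta <- if (length(ctrl_rows) > 0) {
      pmin(pmax(colMeans(y[ctrl_rows, , drop = FALSE]), lo), hi)
    } else rep(mean(c(lo, hi)), Tt)
    alpha <- matrix(0, La, Tt); beta <- matrix(0, Lb, Tt)
    gamma <- matrix(0, La * Lb, Tt)

    for (it in seq_len(n_iter)) {
      effmat <- alpha[a, , drop = FALSE] + beta[b, , drop = FALSE] +
        gamma[cell, , drop = FALSE]
      # zeta | rest: flat within [lo, hi]
      m <- colMeans(y - effmat)
      if (!bound_warned && any(m > hi | m < lo)) {
        warning("data pull the control level outside its prior support [",
                lo, ", ", hi, "]; posterior concentrates at the bound")
        bound_warned <- TRUE
      }
      zeta <- rtruncnorm_vec(m, sqrt(s2 / N), lo, hi)

      zmat <- matrix(zeta, N, Tt, byrow = TRUE)
      for (aa in seq_len(La)[-1]) {
        r <- rows_a[[aa]]
        if (length(r) == 0) {
          alpha[aa, ] <- stats::rnorm(Tt, 0, sqrt(v0)); next
        }
        part <- y[r, , drop = FALSE] - zmat[r, , drop = FALSE] -
          beta[b[r], , drop = FALSE] - gamma[cell[r], , drop = FALSE]
        prec <- length(r) / s2 + 1 / v0
        alpha[aa, ] <- stats::rnorm(Tt, (colSums(part) / s2) / prec,
                                    sqrt(1 / prec))
      }
      for (bb in seq_len(Lb)[-1]) {
        r <- rows_b[[bb]]
        if (length(r) == 0) {
          beta[bb, ] <- stats::rnorm(Tt, 0, sqrt(v0)); next
        }
        part <- y[r, , drop = FALSE] - zmat[r, , drop = FALSE] -
          alpha[a[r], , drop = FALSE] - gamma[cell[r], , drop = FALSE]
        prec <- length(r) / s2 + 1 / v0
        beta[bb, ] <- stats::rnorm(Tt, (colSums(part) / s2) / prec,
                                   sqrt(1 / prec))
      }
      for (cc in noncontrol_cells) {
        r <- rows_g[[cc]]
        if (length(r) == 0) {
          gamma[cc, ] <- stats::rnorm(Tt, 0, sqrt(v0)); next
        }
        part <- y[r, , drop = FALSE] - zmat[r, , drop = FALSE] -
          alpha[a[r], , drop = FALSE] - beta[b[r], , drop = FALSE]
        prec <- length(r) / s2 + 1 / v0
        gamma[cc, ] <- stats::rnorm(Tt, (colSums(part) / s2) / prec,
                                    sqrt(1 / prec))
      }
      if (estimate_sigma) {
        mu <- zmat + alpha[a, , drop = FALSE] + beta[b, , drop = FALSE] +
          gamma[cell, , drop = FALSE]
        rss <- sum((y - mu)^2)
        s2 <- 1 / stats::rgamma(1, 0.001 + N * Tt / 2, 0.001 + rss / 2)
      }
      if (it > burn_in) {
        row <- (ch - 1) * keep + (it - burn_in)
        draws$zeta[row, ] <- zeta
        for (aa in seq_len(La)[-1]) {
          draws[[paste0("alpha", aa)]][row, ] <- alpha[aa, ]
        }
        for (bb in seq_len(Lb)[-1]) {
          draws[[paste0("beta", bb)]][row, ] <- beta[bb, ]
        }
        for (aa in seq_len(La)[-1]) for (bb in seq_len(Lb)[-1]) {
          draws[[paste0("gamma", aa, "_", bb)]][row, ] <-
            gamma[(aa - 1) * Lb + bb, ]
        }
        if (estimate_sigma) sigma2_draws[row] <- s2
      }
    }
  }

  structure(
    list(
      substrate = input$substrate, draws = draws, effects = eff,
      tstar = input$tstar, sigma2 = sigma2, sigma2_draws = sigma2_draws,
      n_iter = n_iter, burn_in = burn_in, n_chains = n_chains, seed = seed,
      zeta_support = zeta_support
    ),
    class = "pm_effect_chains"
  )
}

#' Posterior summaries of the effect chains
#'
#' Per effect and time point: posterior mean and equal-tailed credible
#' interval; an effect (never the control level) is flagged significant
#' when its interval excludes zero.
#'
#' @param chains a `pm_effect_chains`.
#' @param level credible level, default 0.95.
#' @return data frame with columns `substrate`, `effect_type`,
#'   `level_a`, `level_b`, `time`, `mean`, `lower`, `upper`,
#'   `significant`.
#' @export
summarize_effects <- function(chains, level = 0.95) {
  alpha2 <- (1 - level) / 2
  out <- NULL
  for (k in seq_len(nrow(chains$effects))) {
    nm <- chains$effects$name[k]
    d <- chains$draws[[nm]]
    q <- apply(d, 2, stats::quantile, probs = c(alpha2, 1 - alpha2),
               names = FALSE)
    typ <- chains$effects$type[k]
    out <- rbind(out, data.frame(
      substrate = chains$substrate %||% NA_character_,
      effect_type = typ,
      level_a = chains$effects$level_a[k],
      level_b = chains$effects$level_b[k],
      time = format(chains$tstar, trim = TRUE),
      mean = colMeans(d), lower = q[1, ], upper = q[2, ],
      significant = if (typ == "control") NA else q[1, ] > 0 | q[2, ] < 0,
      stringsAsFactors = FALSE
    ))
  }
  rownames(out) <- NULL
  out
}

#' Time-averaged effect estimates
#'
#' For each posterior draw the effect is averaged over the thinned time
#' points, and the derived chain is summarized like any other. Averaging
#' gives a quick overall picture but cancels effects that change sign
#' over time, so it complements rather than replaces the time-point-wise
#' estimates.
#'
#' @inheritParams summarize_effects
#' @return data frame in the shape of [summarize_effects()] with
#'   `time = "averaged"`.
#' @export
average_over_time <- function(chains, level = 0.95) {
  alpha2 <- (1 - level) / 2
  out <- NULL
  for (k in seq_len(nrow(chains$effects))) {
    nm <- chains$effects$name[k]
    d <- rowMeans(chains$draws[[nm]])
    q <- stats::quantile(d, probs = c(alpha2, 1 - alpha2), names = FALSE)
    typ <- chains$effects$type[k]
    out <- rbind(out, data.frame(
      substrate = chains$substrate %||% NA_character_,
      effect_type = typ,
      level_a = chains$effects$level_a[k],
      level_b = chains$effects$level_b[k],
      time = "averaged",
      mean = mean(d), lower = q[1], upper = q[2],
      significant = if (typ == "control") NA else q[1] > 0 | q[2] < 0,
      stringsAsFactors = FALSE
    ))
  }
  rownames(out) <- NULL
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Effect identification for every substrate of an experiment
#'
#' Runs [build_effect_input()], [sample_effects()],
#' [summarize_effects()] and [average_over_time()] for each well of the
#' (normalized) experiment and stacks the results.
#'
#' @param normalization a [normalize_experiment()] result (or a list
#'   with `experiment` and `labels`).
#' @param tstar thinned time points; default [thin_timepoints()] of the
#'   experiment grid.
#' @param wells wells to analyse; default all wells of the first plate.
#' @param ... passed to [sample_effects()] (`sigma2`, `n_iter`,
#'   `burn_in`, `n_chains`, `seed`, ...).
#' @param level credible level.
#' @return data frame of per-time-point and time-averaged summaries for
#'   every analysed well.
#' @export
run_effects <- function(normalization, tstar = NULL, wells = NULL,
                        level = 0.95, ...) {
  experiment <- normalization$experiment
  design <- pm_design(experiment)
  if (is.null(tstar)) tstar <- thin_timepoints(experiment$times)
  if (is.null(wells)) wells <- experiment$plates[[1]]$wells
  out <- lapply(wells, function(w) {
    inp <- build_effect_input(experiment, normalization$labels, w, tstar)
    ch <- sample_effects(inp, design, ...)
    rbind(summarize_effects(ch, level), average_over_time(ch, level))
  })
  do.call(rbind, out)
}

#' Benjamini-Hochberg adjustment of significance across substrates
#'
#' Optional helper: converts each effect's credible interval into a
#' pseudo p-value (the smallest level at which the equal-tailed interval
#' excludes zero cannot be recovered from the summary alone, so the
#' posterior tail probability of the wrong sign is approximated from the
#' normal summary) and applies [stats::p.adjust()] across substrates.
#' Off by default; the primary significance call remains the unadjusted
#' 95% interval.
#'
#' @param summary data frame from [run_effects()].
#' @param level credible level used for the intervals.
#' @return the data frame with an extra logical column
#'   `significant_bh`.
#' @export
adjust_significance <- function(summary, level = 0.95) {
  sdv <- (summary$upper - summary$lower) /
    (2 * stats::qnorm(1 - (1 - level) / 2))
  p <- 2 * stats::pnorm(-abs(summary$mean) / pmax(sdv, 1e-12))
  p[summary$effect_type == "control"] <- NA
  summary$significant_bh <- stats::p.adjust(p, method = "BH") < (1 - level)
  summary$significant_bh[summary$effect_type == "control"] <- NA
  summary
}

#' Write an effects summary to CSV
#'
#' @param summary data frame from [run_effects()].
#' @param file output path.
#' @return `summary`, invisibly.
#' @export
write_effects <- function(summary, file) {
  utils::write.csv(summary, file, row.names = FALSE, quote = FALSE)
  invisible(summary)
}
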