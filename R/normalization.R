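#' Stabilize activity labels across replicates
#'
#' Replicated arrays of the same condition occasionally disagree on a
#' well's activity label; a label seen in only a minority of replicates
#' is likely a false signal. Stabilization gives each well the label
#' `"active"` in every replicate when the fraction of replicates calling
#' it active is at least `proportion`, otherwise `"non-active"` in every
#' replicate. Afterwards all replicates of the condition share one label
#' vector (and hence the same active count).
#'
#' @param labels_list list of named label vectors (one per replicate of
#'   one condition), all over the same wells.
#' @param proportion required fraction of replicates, in (0, 1];
#'   default 0.5 (an exact half counts as active).
#' @return list of label vectors of the same shape, now identical across
#'   replicates.
#' @export
stabilize_labels <- function(labels_list, proportion = 0.5) {
  stopifnot(length(labels_list) >= 1, proportion > 0, proportion <= 1)
  wells <- names(labels_list[[1]])
  for (l in labels_list) {
    if (!identical(sort(names(l)), sort(wells))) {
      stop("replicates have mismatched well sets")
    }
  }
  frac <- rowMeans(vapply(labels_list,
                          function(l) l[wells] == "active",
                          logical(length(wells))))
  common <- stats::setNames(
    ifelse(frac >= proportion, "active", "non-active"), wells
  )
  lapply(labels_list, function(l) common)
}

#' Fit group base curves for one plate
#'
#' The base curve of a group is the single curve fitted to the pooled
#' points of all of the group's wells on one array: a logistic curve for
#' the active group (with linear fallback) and a line for the non-active
#' group, both truncated at zero on the plate's time grid.
#'
#' @param plate a [pm_plate()].
#' @param labels named label vector covering all wells of the plate.
#' @return list with elements `active` and `non-active`, each either
#'   `NULL` (empty group) or a list with `group`, `values`
#'   (zero-truncated base curve on the time grid) and `source_fit`
#'   (the [fit_profile()] result).
#' @export
fit_base_curves <- function(plate, labels) {
  stopifnot(inherits(plate, "pm_plate"))
  if (!all(plate$wells %in% names(labels))) {
    stop("labels must cover all wells of the plate")
  }
  labels <- labels[plate$wells]
  one <- function(group) {
    rows <- labels == group
    if (!any(rows)) return(NULL)
    fit <- fit_profile(
      rep(plate$times, times = sum(rows)),
      as.vector(t(plate$signals[rows, , drop = FALSE])),
      label = group, eval_times = plate$times
    )
    list(group = group, values = fit$fitted, source_fit = fit)
  }
  list("active" = one("active"), "non-active" = one("non-active"))
}

#' Select the reference array of one group within one condition
#'
#' The reference is the replicate closest to the others, where the
#' distance between two arrays is the Euclidean distance between their
#' base curves (as vectors over the full time grid) and an array's score
#' is the sum of its distances to all other arrays. Ties break to the
#' smallest array id, so the choice is deterministic.
#'
#' @param bases named list (array id -> base curve list as returned by
#'   [fit_base_curves()], entries for one group only); `NULL` entries
#'   (arrays lacking the group) are ignored.
#' @return the chosen array id, or `NA_character_` when no array has the
#'   group.
#' @export
select_reference <- function(bases) {
  bases <- bases[!vapply(bases, is.null, logical(1))]
  if (length(bases) == 0) return(NA_character_)
  ids <- sort(names(bases))
  if (length(ids) == 1) return(ids)
  vals <- vapply(bases[ids], `[[`, numeric(length(bases[[1]]$values)), "values")
  score <- vapply(ids, function(i) {
    sum(sqrt(colSums((vals - vals[, i])^2)))
  }, numeric(1))
  ids[which.min(score)]  # ids sorted, so first minimum = smallest id
}

#' Normalization factor of one array relative to the reference
#'
#' The ratio of the time-summed reference base curve to the time-summed
#' base curve of the array being normalized; multiplying the array's
#' signals by this factor brings its group to the reference's level.
#'
#' @param ref_base,arr_base base curve lists (see [fit_base_curves()]).
#' @return positive scalar.
#' @export
normalization_factor <- function(ref_base, arr_base) {
  s <- sum(arr_base$values)
  if (!is.finite(s) || s <= 0) {
    stop("degenerate base curve: time-summed values are not positive")
  }
  sum(ref_base$values) / s
}

#' Normalize an experiment across replicates
#'
#' For every condition (setup) and every group (active / non-active): a
#' base curve is fitted per replicate array, a reference array is chosen
#' with [select_reference()], and every other array's wells belonging to
#' that group are multiplied by the array's normalization factor
#' ([normalization_factor()]). Negative normalized values are truncated
#' to zero. References for the active and non-active groups are chosen
#' independently. A condition with a single replicate is left unchanged
#' (factor 1) with a warning.
#'
#' @param experiment a [pm_experiment()].
#' @param groupings list of `pm_grouping`, one per plate (named or in
#'   plate order).
#' @param stabilize use stabilized labels (default `TRUE`); base curves
#'   are re-fitted under the stabilized labels.
#' @param proportion stabilization proportion, see [stabilize_labels()].
#' @return an object of class `pm_normalization`: a list with
#'   `experiment` (the normalized [pm_experiment()]), `factors` (data
#'   frame: setup, factor_a, factor_b, group, array_id, reference flag,
#'   nf), `labels` (named list array id -> labels actually used) and
#'   `stabilized`.
#' @export
normalize_experiment <- function(experiment, groupings, stabilize = TRUE,
                                 proportion = 0.5) {
  stopifnot(inherits(experiment, "pm_experiment"))
  ids <- names(experiment$plates)
  if (is.null(names(groupings))) {
    names(groupings) <- vapply(groupings, `[[`, "", "array_id")
  }
  if (!all(ids %in% names(groupings))) {
    stop("groupings must cover every plate of the experiment")
  }
  labels <- lapply(groupings[ids], `[[`, "labels")

  setups <- experiment_setups(experiment)
  factors_tab <- NULL
  norm_plates <- experiment$plates

  for (s in seq_along(setups)) {
    arr <- setups[[s]]
    if (stabilize && length(arr) >= 2) {
      labels[arr] <- stabilize_labels(labels[arr], proportion)
    }
    bases <- lapply(experiment$plates[arr], function(p) {
      fit_base_curves(p, labels[[p$array_id]])
    })
    single <- length(arr) == 1
    if (single) {
      warning("setup ", s, " has a single replicate; normalization factors set to 1")
    }
    for (group in c("active", "non-active")) {
      gb <- lapply(bases, `[[`, group)
      ref <- if (single) arr else select_reference(gb)
      if (is.na(ref)) next
      for (j in arr) {
        nf <- if (single || is.null(gb[[j]])) 1 else
          normalization_factor(gb[[ref]], gb[[j]])
        rows <- names(which(labels[[j]] == group))
        rows <- intersect(rows, norm_plates[[j]]$wells)
        if (length(rows) > 0) {
          norm_plates[[j]]$signals[rows, ] <-
            pmax(norm_plates[[j]]$signals[rows, , drop = FALSE] * nf, 0)
        }
        factors_tab <- rbind(factors_tab, data.frame(
          setup = s,
          factor_a = experiment$plates[[j]]$factor_a,
          factor_b = experiment$plates[[j]]$factor_b,
          group = group, array_id = j,
          reference = identical(j, ref), nf = nf,
          stringsAsFactors = FALSE
        ))
      }
    }
  }

  out <- experiment
  out$plates <- norm_plates
  structure(
    list(experiment = out, factors = factors_tab, labels = labels,
         stabilized = stabilize),
    class = "pm_normalization"
  )
}

#' @export
print.pm_normalization <- function(x, ...) {
  cat(sprintf(
    "Normalized PM experiment (%s labels): factors in [%.3f, %.3f]\n",
    if (x$stabilized) "stabilized" else "raw", min(x$factors$nf),
    max(x$factors$nf)
  ))
  print(x$factors)
  invisible(x)
}

#' Write normalization factors to CSV
#'
#' @param normalization a `pm_normalization`.
#' @param file output path.
#' @return the factors data frame, invisibly.
#' @export
write_factors <- function(normalization, file) {
  utils::write.csv(normalization$factors, file, row.names = FALSE,
                   quote = FALSE)
  invisible(normalization$factors)
}
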