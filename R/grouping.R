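#' Is a profile entirely below an activity threshold?
#'
#' @param signal numeric vector of one well's signals.
#' @param threshold activity threshold (signal units).
#' @return `TRUE` iff the signal is strictly below `threshold` at every
#'   time point.
#' @export
below_threshold <- function(signal, threshold) {
  stopifnot(is.finite(threshold))
  all(signal < threshold)
}

#' Classify the wells of one plate as active or non-active
#'
#' Hard-assignment EM over a logistic/linear mixture, run separately on
#' each array. Profiles that stay strictly below the user-given
#' `threshold` at every time point are peremptorily labeled non-active;
#' if that covers the whole plate the EM step is skipped entirely (this
#' is how a plate with no metabolic activity at all is handled).
#' Otherwise the threshold (or, without one, a random coin flip per
#' well) provides the initial labels, and the algorithm alternates:
#'
#' * M-step: fit one logistic base curve to the pooled points of all
#'   active wells (linear fallback if the logistic fit fails) and one
#'   line to the pooled points of all non-active wells, both truncated
#'   at zero;
#' * E-step: assign every well to the base curve with the smaller
#'   residual sum of squares, except that below-threshold wells always
#'   stay non-active; ties go to non-active.
#'
#' Iteration stops when the labels no longer change or `max_iter` is
#' reached. If the active group empties mid-run the plate is declared
#' all non-active.
#'
#' @param plate a [pm_plate()].
#' @param threshold optional activity threshold; `NULL` means no
#'   thresholding and random initialization.
#' @param max_iter maximum EM iterations.
#' @param seed optional seed for the random initialization (only used
#'   when `threshold` is `NULL`).
#' @return an object of class `pm_grouping`: a list with `labels`
#'   (named character vector, `"active"`/`"non-active"`), `active_base`
#'   and `nonactive_base` ([fit_profile()] results, `NULL` when the
#'   group is empty), `n_iter`, `converged`, and `sse_trace` (total
#'   residual sum of squares after each M-step).
#' @export
group_plate <- function(plate, threshold = NULL, max_iter = 50, seed = NULL) {
  stopifnot(inherits(plate, "pm_plate"))
  if (length(plate$wells) == 0) stop("plate has no wells")
  times <- plate$times
  sig <- plate$signals
  wells <- plate$wells
  n <- length(wells)

  below <- if (is.null(threshold)) rep(FALSE, n) else
    apply(sig, 1, below_threshold, threshold = threshold)

  finish <- function(labels, active_base, nonactive_base, n_iter, converged,
                     sse_trace) {
    structure(
      list(
        array_id = plate$array_id,
        labels = stats::setNames(labels, wells),
        active_base = active_base, nonactive_base = nonactive_base,
        n_iter = n_iter, converged = converged, sse_trace = sse_trace
      ),
      class = "pm_grouping"
    )
  }

  all_nonactive <- function(n_iter, converged, sse_trace = numeric(0)) {
    base <- fit_profile(rep(times, each = n), as.vector(t(sig)),
                        "non-active", eval_times = times)
    finish(rep("non-active", n), NULL, base, n_iter, converged, sse_trace)
  }

  if (all(below)) {
    # every profile under the threshold: no EM needed
    return(all_nonactive(n_iter = 0L, converged = TRUE))
  }

  # initial labels
  if (!is.null(threshold)) {
    active <- !below
  } else {
    if (!is.null(seed)) set.seed(seed)
    active <- stats::runif(n) < 0.5
    if (!any(active)) active[which.max(rowMeans(sig))] <- TRUE
    if (all(active)) active[which.min(rowMeans(sig))] <- FALSE
  }

  pooled_fit <- function(rows, label) {
    k <- sum(rows)
    fit_profile(rep(times, times = k), as.vector(t(sig[rows, , drop = FALSE])),
                label, eval_times = times)
  }
  well_sse <- function(base_values) {
    rowSums(sweep(sig, 2, base_values, "-")^2)
  }

  sse_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  active_base <- NULL
  nonactive_base <- NULL
  all_active_seen <- FALSE
  repeat {
    iter <- iter + 1L
    # M-step
    active_base <- pooled_fit(active, "active")
    nonactive_base <- if (any(!active)) pooled_fit(!active, "non-active") else NULL
    # orientation: "active" is by definition the group with the stronger
    # signal; a random start can converge to the label-swapped mode
    # (the logistic can mimic a flat line), so swap and refit if needed
    if (!is.null(nonactive_base) &&
        sum(active_base$fitted) < sum(nonactive_base$fitted) &&
        is.null(threshold)) {
      active <- !active
      active_base <- pooled_fit(active, "active")
      nonactive_base <- pooled_fit(!active, "non-active")
    }
    sse_a <- well_sse(active_base$fitted)
    sse_n <- if (is.null(nonactive_base)) rep(Inf, n) else
      well_sse(nonactive_base$fitted)
    sse_trace <- c(sse_trace, sum(ifelse(active, sse_a, sse_n)))
    # E-step: smaller SSE wins, ties and below-threshold wells non-active
    new_active <- sse_a < sse_n & !below
    if (!any(new_active)) {
      return(all_nonactive(n_iter = iter, converged = TRUE,
                           sse_trace = sse_trace))
    }
    if (all(new_active)) {
      # the non-active group died: with both groups fitted to mixed
      # pools this can be an artefact of a poor start, so re-seed the
      # group with the weakest well once; if the E-step empties it
      # again, accept the all-active solution
      if (all_active_seen) {
        converged <- TRUE
        active <- new_active
        break
      }
      all_active_seen <- TRUE
      new_active[which.min(rowMeans(sig))] <- FALSE
      active <- new_active
      if (iter >= max_iter) break
      next
    }
    if (identical(new_active, active)) {
      converged <- TRUE
      active <- new_active
      break
    }
    active <- new_active
    if (iter >= max_iter) break
  }

  if (all(active)) nonactive_base <- NULL
  finish(ifelse(active, "active", "non-active"),
         active_base, nonactive_base, iter, converged, sse_trace)
}

#' Number of active wells in a grouping
#'
#' @param grouping a `pm_grouping` or a labels vector.
#' @return integer count of wells labeled `"active"`.
#' @export
count_active <- function(grouping) {
  labels <- if (inherits(grouping, "pm_grouping")) grouping$labels else grouping
  sum(labels == "active")
}

#' @export
print.pm_grouping <- function(x, ...) {
  cat(sprintf(
    "Grouping of array '%s': %d active / %d non-active (%d EM iterations%s)\n",
    x$array_id, count_active(x), sum(x$labels == "non-active"), x$n_iter,
    if (x$converged) ", converged" else ""
  ))
  invisible(x)
}

#' Write well labels to CSV
#'
#' @param groupings list of `pm_grouping` (or a single one).
#' @param file output path.
#' @return the labels data frame, invisibly.
#' @export
write_labels <- function(groupings, file) {
  if (inherits(groupings, "pm_grouping")) groupings <- list(groupings)
  tab <- do.call(rbind, lapply(groupings, function(g) {
    data.frame(array_id = g$array_id, well = names(g$labels),
               label = unname(g$labels), stringsAsFactors = FALSE)
  }))
  utils::write.csv(tab, file, row.names = FALSE, quote = FALSE)
  invisible(tab)
}
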