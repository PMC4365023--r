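#' Logistic growth curve
#'
#' Evaluates the three-parameter logistic model
#' \deqn{F(t) = Asym / (1 + \exp((xmid - t)/scale))}
#' used to describe active metabolic profiles: `asym` is the signal as
#' t tends to infinity, `xmid` the time at which the signal reaches
#' `asym / 2`, and `scale` the inverse of the maximum growth rate.
#'
#' @param t numeric vector of times (hours).
#' @param asym asymptotic signal level (signal units).
#' @param xmid inflection time (hours).
#' @param scale inverse maximum growth rate (hours).
#' @return numeric vector of model values at `t`.
#' @export
logistic_curve <- function(t, asym, xmid, scale) {
  asym / (1 + exp((xmid - t) / scale))
}

#' Fit failure condition
#'
#' Signalled by [fit_logistic()] when the optimizer does not converge,
#' returns non-finite parameters, or estimates a non-positive asymptote.
#' Callers such as [fit_profile()] catch this condition and fall back to
#' the linear model.
#' @param message description of the failure.
#' @keywords internal
pm_fit_failure <- function(message) {
  structure(
    class = c("pm_fit_failure", "error", "condition"),
    list(message = message, call = sys.call(-1))
  )
}

# Self-starting heuristic for the logistic fit: asym from the signal
# maximum, xmid from the first half-maximum crossing, scale from the
# 25%-75% rise time (floored at one grid step). When several profiles are
# pooled the heuristic works on per-time-point means.
logistic_start <- function(times, signal) {
  if (anyDuplicated(times)) {
    m <- tapply(signal, times, mean)
    tt <- as.numeric(names(m))
    ss <- as.numeric(m)
    o <- order(tt)
    tt <- tt[o]; ss <- ss[o]
  } else {
    tt <- times; ss <- signal
  }
  smax <- max(ss)
  step <- if (length(tt) > 1) min(diff(sort(tt))) else 1
  first_t_at <- function(frac) {
    idx <- which(ss >= frac * smax)
    if (length(idx) == 0) tt[length(tt)] else tt[min(idx)]
  }
  xmid0 <- first_t_at(0.5)
  scale0 <- max((first_t_at(0.75) - first_t_at(0.25)) / 2, step)
  c(asym = smax, xmid = xmid0, scale = scale0)
}

#' Fit the logistic model to a metabolic profile
#'
#' Least-squares estimation of `(asym, xmid, scale)` by Levenberg-Marquardt
#' damped least squares ([minpack.lm::nls.lm]). `times` may contain
#' duplicates, so several pooled profiles can be fitted jointly (used for
#' group base curves).
#'
#' @param times numeric vector of observation times (hours).
#' @param signal numeric vector of signals, same length as `times`.
#' @param max_iter maximum optimizer iterations.
#' @return an object of class `pm_logistic_fit`: a list with elements
#'   `asym`, `xmid`, `scale` and `residual_sd`.
#' @section Failure: non-convergence, non-finite estimates, or an
#'   estimated `asym <= 0` raise a `pm_fit_failure` condition; `scale` is
#'   deliberately not sign-constrained so decreasing profiles remain
#'   representable.
#' @export
fit_logistic <- function(times, signal, max_iter = 200) {
  stopifnot(length(times) == length(signal))
  if (length(times) < 4) stop("logistic fit needs at least 4 points")
  if (!all(is.finite(times)) || !all(is.finite(signal))) {
    stop("non-finite values in logistic fit input")
  }
  start <- logistic_start(times, signal)
  resid_fn <- function(p) {
    signal - logistic_curve(times, p[1], p[2], p[3])
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start, fn = resid_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = max_iter, ptol = 1e-8, ftol = 1e-10
      )
    ),
    error = function(e) NULL
  )
  # info codes 1:3 indicate convergence in ftol/ptol terms; 0 and >4 are
  # failures (maxiter reached counts as non-convergence)
  if (is.null(fit) || !fit$info %in% 1:4 ||
      !all(is.finite(fit$par)) || fit$par[1] <= 0) {
    stop(pm_fit_failure("logistic fit failed"))
  }
  p <- fit$par
  res <- resid_fn(p)
  dfree <- max(length(res) - 3, 1)
  structure(
    list(
      asym = unname(p[1]), xmid = unname(p[2]), scale = unname(p[3]),
      residual_sd = sqrt(sum(res^2) / dfree)
    ),
    class = "pm_logistic_fit"
  )
}

#' Fit the linear model to a metabolic profile
#'
#' Ordinary least squares for the line `b0 + b1 * t` describing
#' non-active profiles (and the fallback for active profiles on which the
#' logistic fit fails).
#'
#' @inheritParams fit_logistic
#' @return an object of class `pm_linear_fit`: a list with elements
#'   `b0` (starting level), `b1` (slope, signal units per hour) and
#'   `residual_sd`.
#' @export
fit_linear <- function(times, signal) {
  stopifnot(length(times) == length(signal))
  if (length(times) < 2) stop("linear fit needs at least 2 points")
  if (!all(is.finite(times)) || !all(is.finite(signal))) {
    stop("non-finite values in linear fit input")
  }
  X <- cbind(1, times)
  cf <- stats::lm.fit(X, signal)$coefficients
  res <- signal - X %*% cf
  dfree <- max(length(signal) - 2, 1)
  structure(
    list(
      b0 = unname(cf[1]), b1 = unname(cf[2]),
      residual_sd = sqrt(sum(res^2) / dfree)
    ),
    class = "pm_linear_fit"
  )
}

#' Fit a profile according to its activity label
#'
#' Active profiles get the logistic model, with an automatic linear
#' fallback if the logistic fit fails; non-active profiles get the linear
#' model. Fitted values on `times` are truncated at zero, since negative
#' metabolic signals are not biologically meaningful.
#'
#' @inheritParams fit_logistic
#' @param label `"active"` or `"non-active"`.
#' @param eval_times times at which the `fitted` element is evaluated;
#'   defaults to the unique sorted `times`.
#' @return an object of class `pm_profile_fit`: a list with elements
#'   `kind` (`"logistic"` or `"linear"`), `params` (the underlying fit),
#'   `fitted` (zero-truncated model values on `eval_times`), `times`
#'   (= `eval_times`) and `fallback_used`.
#' @export
fit_profile <- function(times, signal, label = c("active", "non-active"),
                        eval_times = NULL) {
  label <- match.arg(label)
  if (is.null(eval_times)) eval_times <- sort(unique(times))
  fallback <- FALSE
  if (label == "active") {
    params <- tryCatch(fit_logistic(times, signal),
                       pm_fit_failure = function(e) NULL)
    if (is.null(params)) {
      params <- fit_linear(times, signal)
      fallback <- TRUE
    }
  } else {
    params <- fit_linear(times, signal)
  }
  kind <- if (inherits(params, "pm_logistic_fit")) "logistic" else "linear"
  structure(
    list(
      kind = kind, params = params,
      fitted = pmax(evaluate_fit(params, eval_times), 0),
      times = eval_times, fallback_used = fallback
    ),
    class = "pm_profile_fit"
  )
}

#' Evaluate a fitted kinetic model
#'
#' @param fit a `pm_logistic_fit`, `pm_linear_fit` or `pm_profile_fit`.
#' @param times numeric vector of times at which to evaluate.
#' @return numeric vector of model values; for a `pm_profile_fit` the
#'   values are truncated at zero.
#' @export
evaluate_fit <- function(fit, times) {
  UseMethod("evaluate_fit")
}

#' @export
evaluate_fit.pm_logistic_fit <- function(fit, times) {
  logistic_curve(times, fit$asym, fit$xmid, fit$scale)
}

#' @export
evaluate_fit.pm_linear_fit <- function(fit, times) {
  fit$b0 + fit$b1 * times
}

#' @export
evaluate_fit.pm_profile_fit <- function(fit, times) {
  pmax(evaluate_fit(fit$params, times), 0)
}

#' @export
print.pm_logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit: asym = %.4g, xmid = %.4g h, scale = %.4g h (residual sd %.3g)\n",
              x$asym, x$xmid, x$scale, x$residual_sd))
  invisible(x)
}

#' @export
print.pm_linear_fit <- function(x, ...) {
  cat(sprintf("Linear fit: b0 = %.4g, b1 = %.4g per h (residual sd %.3g)\n",
              x$b0, x$b1, x$residual_sd))
  invisible(x)
}

#' @export
print.pm_profile_fit <- function(x, ...) {
  cat(sprintf("Profile fit (%s%s)\n", x$kind,
              if (x$fallback_used) ", linear fallback" else ""))
  print(x$params)
  invisible(x)
}
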