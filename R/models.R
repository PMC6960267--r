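#' Two-parameter logistic response probability
#'
#' Probability of a correct response under the two-parameter logistic (2PL)
#' item response model with linear predictor `a * theta - b`.
#'
#' Note the parameterization: the difficulty enters as an *intercept*,
#' `exp(a*theta - b) / (1 + exp(a*theta - b))`, not in the slope-threshold
#' form `a*(theta - b)`. Both conventions are common in the IRT literature;
#' everything in this package uses the intercept form consistently.
#'
#' @param theta ability (unitless), any real.
#' @param a discrimination, must be strictly positive.
#' @param b difficulty intercept (unitless), any real.
#' @return Probability in (0, 1). Vectorized over all arguments (recycled).
#' @examples
#' two_pl(0, 1, 0)            # 0.5
#' two_pl(1, 2, 1)            # plogis(1)
#' @export
two_pl <- function(theta, a, b) {
  check_finite(theta = theta, a = a, b = b)
  if (any(a <= 0)) stop("discrimination 'a' must be > 0")
  stats::plogis(a * theta - b)
}

#' Standardized residual log response time
#'
#' The standardized deviation of an observed log response time from its
#' expectation under the lognormal response-time model:
#' `Z = (log(T) - (beta - tau)) / sigma`.
#'
#' @param log_time log response time (log-seconds).
#' @param beta item time intensity (log-seconds).
#' @param tau person speed (unitless; higher = faster).
#' @param sigma item residual SD of log time, must be > 0.
#' @return Standardized residual (unitless). Vectorized.
#' @export
residual_z <- function(log_time, beta, tau, sigma) {
  check_finite(log_time = log_time, beta = beta, tau = tau, sigma = sigma)
  if (any(sigma <= 0)) stop("'sigma' must be > 0")
  (log_time - (beta - tau)) / sigma
}

#' Speed-accuracy tradeoff response probability (SATM)
#'
#' Probability of a correct response under the speed-accuracy tradeoff
#' response model: the 2PL probability acts as an asymptote that is
#' approached exponentially as the (residual) response time grows,
#' `P = lambda * (1 - exp(-exp(alpha * z + zeta)))` with
#' `lambda = two_pl(theta, a, b)`.
#'
#' For `alpha > 0` the probability increases with `z` (slower-than-expected
#' responses are more accurate) and tends to `lambda` as `z` grows; it can
#' never exceed the ability-determined asymptote, in contrast to
#' [rmm_prob()].
#'
#' @inheritParams two_pl
#' @param alpha item slope of the residual-time effect.
#' @param z standardized residual log response time (see [residual_z()]).
#' @param zeta test-level intercept of the residual-time effect.
#' @return Probability in (0, lambda). Vectorized.
#' @export
satm_prob <- function(theta, a, b, alpha, z, zeta) {
  check_finite(theta = theta, a = a, b = b, alpha = alpha, z = z, zeta = zeta)
  if (any(a <= 0)) stop("discrimination 'a' must be > 0")
  lam <- stats::plogis(a * theta - b)
  lam * time_term(alpha * z + zeta)
}

# 1 - exp(-exp(x)), computed to avoid cancellation near both asymptotes.
time_term <- function(x) {
  -expm1(-exp(pmin(x, 700)))
}

#' Response-moderation response probability (RMM)
#'
#' Comparator model in which the residual log time enters the 2PL linear
#' predictor directly: `P = plogis(a * theta - b + alpha * z)`. Unlike
#' [satm_prob()] this probability approaches 1 for any ability as
#' `alpha * z` grows, i.e. unlimited time can always produce a correct
#' response.
#'
#' @inheritParams satm_prob
#' @return Probability in (0, 1). Vectorized.
#' @export
rmm_prob <- function(theta, a, b, alpha, z) {
  check_finite(theta = theta, a = a, b = b, alpha = alpha, z = z)
  if (any(a <= 0)) stop("discrimination 'a' must be > 0")
  stats::plogis(a * theta - b + alpha * z)
}

#' Lognormal response-time log density
#'
#' Log density of an observed response time `T` (seconds) under the
#' lognormal response-time model `log(T) ~ N(beta - tau, sigma^2)`,
#' including the change-of-variable Jacobian so the density integrates to 1
#' over `T` in (0, Inf).
#'
#' @param time response time in seconds, must be > 0.
#' @inheritParams residual_z
#' @return Log density. Vectorized.
#' @export
lognormal_rt_logpdf <- function(time, beta, tau, sigma) {
  check_finite(time = time, beta = beta, tau = tau, sigma = sigma)
  if (any(time <= 0)) stop("'time' must be > 0")
  if (any(sigma <= 0)) stop("'sigma' must be > 0")
  stats::dnorm(log(time), mean = beta - tau, sd = sigma, log = TRUE) - log(time)
}

#' Exponential speed-accuracy tradeoff curve
#'
#' Accuracy as a function of processing time in the classic speed-accuracy
#' tradeoff experiment: `d(t) = lam * (1 - exp(-phi * (t - delta)))`,
#' defined for `t > delta`.
#'
#' @param t processing time in seconds; must exceed `delta`.
#' @param lam asymptotic accuracy, in (0, 1].
#' @param phi rate of approach to the asymptote (1/seconds), > 0.
#' @param delta intercept time (seconds) below which accuracy is at
#'   chance/zero, >= 0.
#' @return Accuracy values. Vectorized over `t`.
#' @export
sat_curve <- function(t, lam, phi, delta) {
  check_finite(t = t, lam = lam, phi = phi, delta = delta)
  if (lam <= 0 || lam > 1) stop("'lam' must be in (0, 1]")
  if (phi <= 0) stop("'phi' must be > 0")
  if (delta < 0) stop("'delta' must be >= 0")
  if (any(t <= delta)) stop("'t' must be > delta (curve undefined at or below the intercept time)")
  lam * (-expm1(-phi * (t - delta)))
}

#' Least-squares fit of the speed-accuracy tradeoff curve
#'
#' Fits `d(t) = lam * (1 - exp(-phi * (t - delta)))` to condition-level
#' (time, accuracy) pairs by least squares, as done when summarizing a
#' speed-accuracy tradeoff experiment, subject to `lam` in (0, 1],
#' `phi > 0` and `0 <= delta < min(t)`.
#'
#' Optimization uses box-constrained BFGS on `(lam, log(phi), delta)` from a
#' small grid of starting values. A fit is flagged degenerate when the
#' accuracies carry (almost) no time trend, and non-converged when the
#' optimizer fails from every start.
#'
#' @param times strictly increasing vector of processing times (seconds).
#' @param accuracies accuracy at each time, same length, in [0, 1].
#' @return An object of class `sat_fit`: list with elements `lam`, `phi`,
#'   `delta`, `rss` (residual sum of squares), `converged`, `degenerate`
#'   and `fitted`.
#' @examples
#' t <- seq(0.5, 4, length.out = 8)
#' fit <- fit_sat_curve(t, sat_curve(t, lam = 0.9, phi = 2, delta = 0.3))
#' unlist(fit[c("lam", "phi", "delta")])
#' @export
fit_sat_curve <- function(times, accuracies) {
  if (length(times) < 4) stop("need at least 4 (time, accuracy) pairs")
  if (length(times) != length(accuracies)) stop("'times' and 'accuracies' lengths differ")
  check_finite(times = times, accuracies = accuracies)
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")

  degenerate <- stats::sd(accuracies) < 1e-10
  obj <- function(p) {
    lam <- p[1]; phi <- exp(p[2]); delta <- p[3]
    sum((lam * (-expm1(-phi * pmax(times - delta, 1e-12))) - accuracies)^2)
  }
  tmin <- min(times)
  lo <- c(1e-6, log(1e-6), 0)
  hi <- c(1, log(1e6), tmin * (1 - 1e-8))
  starts <- expand.grid(
    lam   = pmin(pmax(max(accuracies), 0.05), 1),
    lphi  = log(c(0.25, 1, 4) / max(tmin, 0.25)),
    delta = c(0, tmin / 2)
  )
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    p0 <- pmin(pmax(as.numeric(starts[k, ]), lo), hi)
    op <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best)) {
    out <- list(lam = NA_real_, phi = NA_real_, delta = NA_real_,
                rss = NA_real_, converged = FALSE, degenerate = degenerate,
                fitted = rep(NA_real_, length(times)))
    class(out) <- "sat_fit"
    return(out)
  }
  lam <- best$par[1]; phi <- exp(best$par[2]); delta <- best$par[3]
  out <- list(lam = lam, phi = phi, delta = delta, rss = best$value,
              converged = best$convergence == 0 && !degenerate,
              degenerate = degenerate,
              fitted = lam * (-expm1(-phi * pmax(times - delta, 1e-12))))
  class(out) <- "sat_fit"
  out
}

#' @export
print.sat_fit <- function(x, ...) {
  cat("Speed-accuracy tradeoff curve fit (least squares)\n")
  cat(sprintf("  lam = %.4f  phi = %.4f /s  delta = %.4f s\n", x$lam, x$phi, x$delta))
  cat(sprintf("  RSS = %.6g  converged: %s%s\n", x$rss, x$converged,
              if (x$degenerate) "  [degenerate: no time trend]" else ""))
  invisible(x)
}

check_finite <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    if (!is.numeric(args[[nm]]) || anyNA(args[[nm]]) || any(!is.finite(args[[nm]])))
      stop(sprintf("'%s' must be finite numeric", nm))
  }
  invisible(TRUE)
}
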