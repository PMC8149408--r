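#' Maximum-likelihood calibration of the modified LCA model
#'
#' Fits the N+3 free parameters \eqn{(\kappa, \beta, I_1, \dots, I_N, \xi)} of
#' the modified LCA model to one observed log-evidence series by maximizing
#' the exact Markov log-likelihood ([lca_loglik]) with the Nelder-Mead simplex
#' algorithm. \eqn{\xi} is optimized on the log scale to enforce positivity;
#' the remaining parameters are unconstrained.
#'
#' To guard against premature simplex collapse, the optimization is iterated:
#' each run's solution seeds the next run's initial simplex, until the largest
#' absolute change across all (natural-scale) parameters between successive
#' runs falls below `restart_tol`, or `max_restarts` is reached (in which case
#' `converged` is `FALSE`).
#'
#' @param x a T x N numeric matrix of log-evidence observations, or an
#'   `"lca_series"` object.
#' @param dt grid step; taken from the series object when `x` is one.
#' @param init starting values: `"auto"` (default; per-component lag-1
#'   moment matching, see Details) or an [lca_params] object.
#' @param restart_tol convergence threshold on the maximum absolute parameter
#'   change between successive optimizer runs (default `1e-6`).
#' @param max_restarts cap on optimizer runs (default 50).
#' @param s series index when `x` holds several series.
#' @param optim_control passed to [stats::optim] `control` (merged over the
#'   defaults `reltol = 1e-8`, `maxit = 200 * n_par`).
#' @details With `init = "auto"`, each coordinate is treated as a scalar OU
#'   process: the pooled lag-1 autoregression slope yields a starting
#'   \eqn{\kappa - \beta}, the regression residual variance yields \eqn{\xi},
#'   and the implied long-run means yield the inputs through the drift fixed
#'   point; \eqn{\beta} starts at half the \eqn{\kappa - \beta} scale. No
#'   knowledge of the generating parameters is used.
#' @return An object of class `"lca_fit"`: list with `estimates` (an
#'   [lca_params]), `loglik`, `n_restarts`, `converged`, `counts` (total
#'   likelihood evaluations), `init`, `series_id`, and the data (`x`, `dt`).
#' @examples
#' p <- lca_params(4, 1, c(0.9, 1.1), 0.25)
#' s <- lca_simulate(p, n_steps = 4000, n_series = 1, seed = 42)
#' f <- lca_fit(s)
#' coef(f)
#' @seealso [lca_aggregate] to summarize fits across many series,
#'   [lca_study] for the full simulate-fit-aggregate pipeline.
#' @export
lca_fit <- function(x, dt = NULL, init = "auto", restart_tol = 1e-6,
                    max_restarts = 50L, s = 1L, optim_control = list()) {
  sm <- as_series_matrix(x, dt, s)
  xm <- sm$x
  dt <- sm$dt
  n <- ncol(xm)
  if (nrow(xm) < 2L) stop("series must contain at least 2 points")
  if (!is.finite(restart_tol) || restart_tol <= 0)
    stop("'restart_tol' must be positive")

  if (identical(init, "auto")) {
    init_params <- lca_auto_init(xm, dt)
  } else if (inherits(init, "lca_params")) {
    if (init$n != n) stop("'init' has the wrong number of alternatives")
    init_params <- init
  } else stop("'init' must be \"auto\" or an lca_params object")

  dI_center <- function(I) I - mean(I)
  theta_of <- function(p) c(p$kappa, p$beta, p$inputs, log(p$xi))
  natural_of <- function(theta) c(theta[1:2], theta[3:(n + 2)], exp(theta[n + 3]))

  nll <- function(theta) {
    kappa <- theta[1]; beta <- theta[2]
    I <- theta[3:(n + 2)]; xi <- exp(theta[n + 3])
    if (!all(is.finite(c(kappa, beta, I, xi))) || xi <= 0) return(1e10)
    a <- kappa - beta
    m <- kappa + beta * (n - 1)
    b1 <- phi_em1(a, dt)
    b2 <- mean(I) * phi_em1(m, dt)
    b5 <- xi^2 / 2 * phi_em1(-2 * a, dt)
    b6 <- xi^2 / (2 * n) * (phi_em1(-2 * m, dt) - phi_em1(-2 * a, dt))
    if (!is.finite(b5) || !is.finite(b6) || b5 <= 0 || b5 + n * b6 <= 0)
      return(1e10)
    f <- b6 / (b5 + n * b6)
    eNb4 <- exp(-n * beta * dt)
    ll <- loglik_sum_cpp(xm, b1 * dI_center(I), b2 * eNb4, (eNb4 - 1) / n,
                         exp(-a * dt), (1 - f) / b5, -f / b5,
                         (n - 1) * log(b5) + log(b5 + n * b6))
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  theta <- theta_of(init_params)
  if (nll(theta) >= 1e10)
    stop("log-likelihood is not finite at the initial values; ",
         "try a different 'init'")
  ctrl <- utils::modifyList(
    list(reltol = 1e-8, maxit = 200L * length(theta)), optim_control)

  n_restarts <- 0L
  converged <- FALSE
  evals <- 0L
  value <- NA_real_
  repeat {
    opt <- stats::optim(theta, nll, method = "Nelder-Mead", control = ctrl)
    n_restarts <- n_restarts + 1L
    evals <- evals + opt$counts[["function"]]
    delta <- max(abs(natural_of(opt$par) - natural_of(theta)))
    theta <- opt$par
    value <- opt$value
    if (delta < restart_tol) { converged <- TRUE; break }
    if (n_restarts >= max_restarts) break
  }

  est <- natural_of(theta)
  est[n + 3] <- max(est[n + 3], .Machine$double.xmin)  # guard log-xi underflow
  structure(
    list(estimates = lca_params(est[1], est[2], est[3:(n + 2)], est[n + 3]),
         loglik = -value, n_restarts = n_restarts, converged = converged,
         counts = evals, init = init_params,
         series_id = if (inherits(x, "lca_series")) s else NA_integer_,
         x = xm, dt = dt, restart_tol = restart_tol),
    class = "lca_fit"
  )
}

#' @export
print.lca_fit <- function(x, ...) {
  cat(sprintf("Modified LCA maximum-likelihood fit (N = %d, %d transitions)\n",
              x$estimates$n, nrow(x$x) - 1L))
  print(signif(coef(x), 6))
  cat(sprintf("log-likelihood %.3f; %d optimizer run(s), %s\n", x$loglik,
              x$n_restarts,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.lca_fit <- function(object, ...) as.vector(object$estimates)

#' @export
logLik.lca_fit <- function(object, ...) {
  structure(object$loglik, df = object$estimates$n + 3L,
            nobs = (nrow(object$x) - 1L), class = "logLik")
}

#' @export
summary.lca_fit <- function(object, ...) {
  r <- residuals(object)
  structure(list(fit = object,
                 resid_mean = colMeans(r), resid_sd = apply(r, 2, stats::sd)),
            class = "summary.lca_fit")
}

#' @export
print.summary.lca_fit <- function(x, ...) {
  print(x$fit)
  cat("standardized one-step residuals (should be ~ N(0,1)):\n")
  print(signif(rbind(mean = x$resid_mean, sd = x$resid_sd), 4))
  invisible(x)
}

#' One-step-ahead conditional means, or the mean at an arbitrary lag
#'
#' With no `x0`, returns the matrix of one-step-ahead conditional means of the
#' fitted series (the model's fitted values). With `x0` and `tau`, returns the
#' conditional mean of the state at lag `tau` from `x0` under the estimated
#' parameters.
#'
#' @param object an `"lca_fit"`.
#' @param x0 optional conditioning state (length-N vector).
#' @param tau lag for the `x0` form; defaults to the data step.
#' @param ... unused.
#' @export
predict.lca_fit <- function(object, x0 = NULL, tau = object$dt, ...) {
  p <- object$estimates
  if (!is.null(x0)) return(cond_mean(p, x0, tau))
  co <- wn_coefficients(p, object$dt)
  xm <- object$x
  xp <- xm[-nrow(xm), , drop = FALSE]
  eNb4 <- exp(p$n * co$b4)
  shift <- co$b2 * eNb4 + co$b1 * input_deviations(p)   # per component
  sweep(xp + (eNb4 - 1) / p$n * rowSums(xp), 2L, shift, "+") * exp(co$b3)
}

#' Standardized one-step innovations of a fitted model
#'
#' The innovation \eqn{d^{(k)} = x^{(k+1)} - E[x^{(k+1)} \mid x^{(k)}]} is
#' whitened with the closed-form square root of the compound-symmetric
#' transition covariance \eqn{2\Omega} (the all-ones direction has variance
#' \eqn{2(b_5 + N b_6)}, the orthogonal complement \eqn{2 b_5}). If the model
#' is correct each entry is standard normal, independent across steps.
#'
#' @param object an `"lca_fit"`.
#' @param ... unused.
#' @return A (T-1) x N matrix.
#' @export
residuals.lca_fit <- function(object, ...) {
  p <- object$estimates
  co <- wn_coefficients(p, object$dt)
  d <- object$x[-1L, , drop = FALSE] - predict(object)
  dbar <- rowMeans(d)
  s1 <- sqrt(2 * (co$b5 + p$n * co$b6))
  s2 <- sqrt(2 * co$b5)
  (d - dbar) / s2 + dbar / s1
}

#' Simulate new series from a fitted model
#'
#' @param object an `"lca_fit"`.
#' @param nsim number of series.
#' @param seed master seed.
#' @param n_steps,dt,x0 as in [lca_simulate]; default to the fitted data's
#'   length, step and first observation.
#' @param ... unused.
#' @return An `"lca_series"` object.
#' @export
simulate.lca_fit <- function(object, nsim = 1L, seed = NULL,
                             n_steps = nrow(object$x), dt = object$dt,
                             x0 = object$x[1L, ], ...) {
  lca_simulate(object$estimates, n_steps = n_steps, dt = dt, x0 = x0,
               n_series = nsim, seed = seed)
}

#' @export
plot.lca_fit <- function(x, ...) {
  r <- residuals(x)
  stats::qqnorm(r, main = "Standardized one-step innovations", ...)
  stats::qqline(r)
  invisible(x)
}

#' Aggregate per-series estimates into a recovery summary
#'
#' Combines maximum-likelihood fits of M independent series into the summary
#' used by the parameter-recovery study: for each parameter, the across-series
#' mean estimate, its standard error (sample standard deviation across series
#' divided by \eqn{\sqrt{M}}), and the z-score mean/SE. Non-converged fits are
#' dropped (with a count kept).
#'
#' @param fits a list of `"lca_fit"` objects with a common N.
#' @return An object of class `"lca_aggregate"`: list with `table` (matrix,
#'   rows = parameters, columns mean/se/z), `estimates` (M x n_par matrix of
#'   per-series estimates), `n_series`, `n_converged`.
#' @export
lca_aggregate <- function(fits) {
  if (!length(fits) || !all(vapply(fits, inherits, TRUE, "lca_fit")))
    stop("'fits' must be a list of lca_fit objects")
  ns <- vapply(fits, function(f) f$estimates$n, 0L)
  if (length(unique(ns)) != 1L)
    stop("all fits must have the same number of alternatives")
  conv <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
  kept <- fits[conv]
  if (length(kept) < 2L)
    stop("need at least 2 converged fits to aggregate")
  est <- t(vapply(kept, coef, coef(kept[[1]])))
  m <- colMeans(est)
  se <- apply(est, 2, stats::sd) / sqrt(nrow(est))
  z <- ifelse(se > 0, m / se, Inf * sign(m))
  structure(
    list(table = cbind(mean = m, se = se, z = z), estimates = est,
         n_series = length(fits), n_converged = length(kept)),
    class = "lca_aggregate"
  )
}

#' @export
print.lca_aggregate <- function(x, ...) {
  cat(sprintf("Across-series estimates (%d of %d fits converged)\n",
              x$n_converged, x$n_series))
  print(signif(x$table, 5))
  invisible(x)
}
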