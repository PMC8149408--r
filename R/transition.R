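# Closed-form transition density of the modified LCA model.
#
# The log-evidence process is a coupled multivariate OU diffusion whose lag-tau
# transition density is Gaussian with compound-symmetric covariance 2*Omega,
# Omega_ij = b5 * delta_ij + b6. The six lag-dependent coefficients b1..b6 come
# from the Wei-Norman product-form solution of the backward Kolmogorov
# equation; everything downstream (mean, covariance, joint and marginal
# densities, likelihood) is expressed through them.

# (e^{a*tau} - 1)/a with a 3rd-order series branch for |a| < 1e-6: the direct
# quotient is 0/0 at a = 0 (kappa = beta, or kappa + beta(N-1) = 0) and loses
# all precision nearby.
phi_em1 <- function(a, tau) {
  if (abs(a) < 1e-6) {
    z <- a * tau
    tau * (1 + z / 2 + z^2 / 6 + z^3 / 24)
  } else {
    (exp(a * tau) - 1) / a
  }
}

#' Wei-Norman coefficients of the transition density
#'
#' Computes the six lag-dependent coefficients \eqn{b_1(\tau), \dots,
#' b_6(\tau)} that parameterize the closed-form Gaussian transition density of
#' the modified LCA log-evidence process. With \eqn{a = \kappa - \beta} and
#' \eqn{m = \kappa + \beta (N - 1)}:
#' \deqn{b_1 = (e^{a\tau} - 1)/a, \quad b_2 = \bar I\,(e^{m\tau} - 1)/m,}
#' \deqn{b_3 = -a\tau, \quad b_4 = -\beta\tau,}
#' \deqn{b_5 = \frac{\xi^2}{4a}(1 - e^{-2a\tau}), \quad
#'       b_6 = \frac{\xi^2}{4N}\left(\frac{1 - e^{-2m\tau}}{m}
#'             - \frac{1 - e^{-2a\tau}}{a}\right).}
#' The removable singularities at \eqn{a \to 0} and \eqn{m \to 0} are handled
#' by series expansion, so the coefficients are continuous in all parameters.
#' All six vanish at \eqn{\tau = 0}; for \eqn{\tau > 0} the covariance
#' \eqn{2\Omega} built from \eqn{b_5, b_6} is positive definite for any real
#' \eqn{\kappa, \beta}.
#'
#' @param params an [lca_params] object.
#' @param tau lag \eqn{\tau \ge 0} (time units of the process).
#' @return An object of class `"lca_wn"`: list with `tau`, `b1`..`b6`, and `n`.
#' @examples
#' p <- lca_params(4, 1, c(0.9, 1.1), 0.25)
#' wn_coefficients(p, tau = 0.5)
#' @export
wn_coefficients <- function(params, tau) {
  stopifnot(inherits(params, "lca_params"))
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau))
    stop("'tau' must be a single finite number")
  if (tau < 0)
    stop("'tau' must be non-negative")
  a <- params$kappa - params$beta
  m <- params$kappa + params$beta * (params$n - 1)
  xi2 <- params$xi^2
  structure(
    list(tau = tau,
         b1 = phi_em1(a, tau),
         b2 = mean(params$inputs) * phi_em1(m, tau),
         b3 = -a * tau,
         b4 = -params$beta * tau,
         b5 = xi2 / 2 * phi_em1(-2 * a, tau),
         b6 = xi2 / (2 * params$n) * (phi_em1(-2 * m, tau) - phi_em1(-2 * a, tau)),
         n = params$n),
    class = "lca_wn"
  )
}

#' @export
print.lca_wn <- function(x, ...) {
  cat(sprintf("Wei-Norman coefficients at lag tau = %g (N = %d)\n", x$tau, x$n))
  b <- unlist(x[paste0("b", 1:6)])
  print(signif(b, 6))
  invisible(x)
}

#' Conditional mean of the transition density
#'
#' Mean of the log-evidence vector at lag `tau` given the earlier state `x0`:
#' \deqn{X_{i0} = \left[x_{i0} + b_2 e^{N b_4} + b_1 \Delta I_i +
#'   \frac{e^{N b_4} - 1}{N} \sum_j x_{j0}\right] e^{b_3}.}
#'
#' @param params an [lca_params] object.
#' @param x0 numeric vector of length N: the conditioning (earlier) state.
#' @param tau lag \eqn{\tau \ge 0}.
#' @param coeffs optional precomputed [wn_coefficients] for this lag.
#' @return Numeric vector of length N.
#' @export
cond_mean <- function(params, x0, tau, coeffs = wn_coefficients(params, tau)) {
  stopifnot(inherits(params, "lca_params"))
  x0 <- as.numeric(x0)
  if (length(x0) != params$n)
    stop(sprintf("'x0' must have length N = %d", params$n))
  if (any(!is.finite(x0)))
    stop("'x0' must be finite")
  eNb4 <- exp(params$n * coeffs$b4)
  dI <- params$inputs - mean(params$inputs)
  (x0 + coeffs$b2 * eNb4 + coeffs$b1 * dI +
      (eNb4 - 1) / params$n * sum(x0)) * exp(coeffs$b3)
}

#' Inverse and log-determinant of the compound-symmetric Omega matrix
#'
#' The transition covariance is \eqn{2\Omega} with \eqn{\Omega_{ij} = b_5
#' \delta_{ij} + b_6}. Because \eqn{\Omega} is a rank-one update of a scaled
#' identity, its inverse and determinant are available in O(1):
#' \deqn{\Omega^{-1} = \frac{1}{b_5}\left(\mathbb{1} -
#'   \frac{b_6}{b_5 + N b_6}\,J\right), \qquad
#'   \det\Omega = b_5^{N-1}(b_5 + N b_6),}
#' where \eqn{J} is the all-ones matrix. The N-by-N matrix is never formed on
#' the likelihood path.
#'
#' @param coeffs an `"lca_wn"` object (or any list with `b5`, `b6`).
#' @param n dimension N.
#' @return List with `inv_diag`, `inv_off` (the diagonal and off-diagonal
#'   entries of \eqn{\Omega^{-1}}) and `logdet` (\eqn{\log\det\Omega}).
#' @export
omega_inverse_logdet <- function(coeffs, n) {
  b5 <- coeffs$b5
  b6 <- coeffs$b6
  if (!is.finite(b5) || !is.finite(b6) || b5 <= 0 || b5 + n * b6 <= 0)
    stop("degenerate covariance: Omega is not positive definite ",
         "(tau too small or zero, or invalid parameters)")
  f <- b6 / (b5 + n * b6)
  list(inv_diag = (1 - f) / b5,
       inv_off = -f / b5,
       logdet = (n - 1) * log(b5) + log(b5 + n * b6))
}

#' Joint transition density of the modified LCA model
#'
#' Log of the exact N-dimensional transition density
#' \deqn{P(x \mid x_0, \tau) = (4\pi)^{-N/2} (\det\Omega)^{-1/2}
#'   \exp\left\{-\tfrac{1}{4}(X_0 - x)^\top \Omega^{-1} (X_0 - x)\right\},}
#' i.e. a Gaussian with mean [cond_mean] and covariance \eqn{2\Omega}. The
#' computation stays in log space and uses the closed-form inverse of the
#' compound-symmetric \eqn{\Omega}, so one evaluation costs O(N).
#'
#' @param x numeric vector of length N: the later state (log evidence).
#' @param x0 numeric vector of length N: the earlier state.
#' @param tau lag \eqn{\tau > 0}; at \eqn{\tau = 0} the density degenerates to
#'   a product of delta functions and an error is raised.
#' @param params an [lca_params] object.
#' @param log logical; return the log density (default) or the density.
#' @return A single numeric value.
#' @examples
#' p <- lca_params(4, 1, c(0.9, 1.1), 0.25)
#' dlca(c(0.1, 0.2), x0 = c(-5, -5), tau = 0.5, params = p)
#' @export
dlca <- function(x, x0, tau, params, log = TRUE) {
  stopifnot(inherits(params, "lca_params"))
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("'tau' must be a single positive number (the density is degenerate at tau = 0)")
  x <- as.numeric(x)
  if (length(x) != params$n)
    stop(sprintf("'x' must have length N = %d", params$n))
  co <- wn_coefficients(params, tau)
  om <- omega_inverse_logdet(co, params$n)
  d <- cond_mean(params, x0, tau, co) - x
  q <- (om$inv_diag - om$inv_off) * sum(d^2) + om$inv_off * sum(d)^2
  ll <- -params$n / 2 * log(4 * pi) - om$logdet / 2 - q / 4
  if (log) ll else exp(ll)
}

#' Marginal transition density of one accumulator
#'
#' Exact one-dimensional marginal of the joint transition density:
#' \deqn{p_i(x_i \mid x_0, \tau) = \frac{1}{\sqrt{4\pi(b_5 + b_6)}}
#'   \exp\left\{-\frac{(X_{i0} - x_i)^2}{4(b_5 + b_6)}\right\},}
#' a Gaussian in \eqn{x_i} with mean \eqn{X_{i0}} and variance
#' \eqn{2(b_5 + b_6)}.
#'
#' @param x_i numeric vector of evaluation points for component `i`
#'   (vectorized).
#' @param i index of the accumulator, 1..N.
#' @param x0 numeric vector of length N: the earlier state.
#' @param tau lag \eqn{\tau > 0}.
#' @param params an [lca_params] object.
#' @param log logical; return log density values.
#' @return Numeric vector the length of `x_i`.
#' @export
dlca_marginal <- function(x_i, i, x0, tau, params, log = FALSE) {
  stopifnot(inherits(params, "lca_params"))
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("'tau' must be a single positive number")
  i <- as.integer(i)
  if (i < 1L || i > params$n)
    stop(sprintf("'i' must be in 1..%d", params$n))
  co <- wn_coefficients(params, tau)
  v <- co$b5 + co$b6
  if (!is.finite(v) || v <= 0)
    stop("degenerate covariance: b5 + b6 must be positive")
  m <- cond_mean(params, x0, tau, co)[i]
  ll <- -0.5 * log(4 * pi * v) - (m - x_i)^2 / (4 * v)
  if (log) ll else exp(ll)
}

#' Map between log evidence and evidence
#'
#' The model is simulated and fitted on the log scale \eqn{x = \ln y}; the
#' positive evidence itself is recovered by `evidence(x) = exp(x)` and mapped
#' back by `log_evidence(y)`, which requires strictly positive input.
#'
#' @param x numeric vector of log evidence.
#' @param y numeric vector of evidence, strictly positive.
#' @return Numeric vector of the same length.
#' @examples
#' evidence(-5)           # the conventional near-zero starting evidence
#' log_evidence(evidence(c(0.3, -2)))
#' @export
evidence <- function(x) {
  if (!is.numeric(x)) stop("'x' must be numeric")
  exp(x)
}

#' @rdname evidence
#' @export
log_evidence <- function(y) {
  if (!is.numeric(y)) stop("'y' must be numeric")
  if (any(!is.finite(y)) || any(y <= 0))
    stop("evidence must be finite and strictly positive")
  log(y)
}
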