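# Exact Markov likelihood of a discretely observed trajectory.

# Coerce the various accepted inputs (matrix, lca_series + index) to a
# T x N matrix plus its step size.
as_series_matrix <- function(x, dt = NULL, s = 1L) {
  if (inherits(x, "lca_series")) {
    list(x = series_matrix(x, s), dt = x$dt)
  } else {
    x <- as.matrix(x)
    if (!is.numeric(x)) stop("series must be numeric")
    if (is.null(dt)) stop("'dt' is required when the series is a plain matrix")
    if (!is.finite(dt) || dt <= 0) stop("'dt' must be positive")
    list(x = x, dt = dt)
  }
}

#' Exact log-likelihood of an observed log-evidence series
#'
#' Because the transition density is available in closed form, the likelihood
#' of a series observed on a uniform grid is the exact Markov product of
#' one-step transitions:
#' \deqn{\ell(\theta) = \sum_{k} \log P(x^{(k+1)} \mid x^{(k)}, \Delta t).}
#' The Wei-Norman coefficients for the single lag \eqn{\Delta t} are computed
#' once and reused for every step; each step then costs O(N).
#'
#' @param params an [lca_params] object.
#' @param x a T x N numeric matrix of log-evidence observations (rows =
#'   times), or an `"lca_series"` object.
#' @param dt grid step; taken from the series object when `x` is one.
#' @param s series index when `x` is an `"lca_series"` with several series.
#' @return The log-likelihood, a single numeric value.
#' @examples
#' p <- lca_params(4, 1, c(0.9, 1.1), 0.25)
#' s <- lca_simulate(p, n_steps = 2000, n_series = 1, seed = 1)
#' lca_loglik(p, s)
#' @export
lca_loglik <- function(params, x, dt = NULL, s = 1L) {
  stopifnot(inherits(params, "lca_params"))
  sm <- as_series_matrix(x, dt, s)
  if (ncol(sm$x) != params$n)
    stop(sprintf("series has %d columns but N = %d", ncol(sm$x), params$n))
  if (nrow(sm$x) < 2L) stop("series must contain at least 2 points")
  if (any(!is.finite(sm$x))) stop("series contains non-finite values")
  co <- wn_coefficients(params, sm$dt)
  om <- omega_inverse_logdet(co, params$n)
  eNb4 <- exp(params$n * co$b4)
  dI <- params$inputs - mean(params$inputs)
  loglik_sum_cpp(sm$x, co$b1 * dI, co$b2 * eNb4, (eNb4 - 1) / params$n,
                 exp(co$b3), om$inv_diag, om$inv_off, om$logdet)
}

# Moment-matching starting values from per-component lag-1 regressions.
# Each coordinate is treated as a scalar OU process: the pooled lag-1
# autoregression slope gives an effective reversion rate used as the
# (kappa - beta) starting value, the residual sd gives xi, and the implied
# long-run means give the inputs via the drift fixed point. beta starts at
# half the (kappa - beta) scale; it is refined by the optimizer.
lca_auto_init <- function(x, dt) {
  n <- ncol(x)
  xp <- x[-nrow(x), , drop = FALSE]
  xn <- x[-1L, , drop = FALSE]
  rho <- numeric(n); icpt <- numeric(n); rvar <- numeric(n)
  for (i in seq_len(n)) {
    v <- stats::var(xp[, i])
    if (!is.finite(v) || v <= 0)
      stop("degenerate series (a coordinate is constant); ",
           "supply an explicit 'init'")
    b <- stats::cov(xp[, i], xn[, i]) / v
    a <- mean(xn[, i]) - b * mean(xp[, i])
    rho[i] <- b; icpt[i] <- a
    rvar[i] <- mean((xn[, i] - a - b * xp[, i])^2)
  }
  rho_bar <- min(max(mean(rho), 1e-3), 1 - 1e-6)
  g <- -log(rho_bar) / dt                       # effective rate kappa - beta
  xi0 <- sqrt(max(mean(rvar), 1e-12) * 2 * g / (1 - rho_bar^2))
  mu <- icpt / pmax(1 - rho, 1e-6)              # long-run mean per coordinate
  beta0 <- 0.5 * g
  kappa0 <- g + beta0
  I0 <- (kappa0 - beta0) * mu + beta0 * sum(mu)
  lca_params(kappa0, beta0, I0, xi0)
}
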