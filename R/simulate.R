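# Monte Carlo simulation of log-evidence trajectories.

#' Drift of the log-evidence process
#'
#' Drift vector \eqn{a_i = I_i - (\kappa - \beta) x_i - \beta \sum_j x_j},
#' algebraically identical to \eqn{I_i - \kappa x_i - \beta \sum_{j \ne i}
#' x_j}: the inhibition sum includes the self term, compensated by the
#' \eqn{(\kappa - \beta)} coefficient.
#'
#' @param params an [lca_params] object.
#' @param x numeric state vector of length N.
#' @return Numeric vector of length N.
#' @export
lca_drift <- function(params, x) {
  stopifnot(inherits(params, "lca_params"))
  x <- as.numeric(x)
  if (length(x) != params$n)
    stop(sprintf("'x' must have length N = %d", params$n))
  params$inputs - (params$kappa - params$beta) * x - params$beta * sum(x)
}

#' Correlated noise increments for the order-1.5 Taylor scheme
#'
#' Draws, per component, \eqn{\Delta W = U_1 \sqrt{\Delta t}} and
#' \eqn{\Delta Z = \tfrac{1}{2} \Delta t^{3/2} (U_1 + U_2/\sqrt 3)} from
#' independent standard normals \eqn{U_1, U_2}, so that
#' \eqn{E(\Delta Z^2) = \tfrac{1}{3}\Delta t^3} and
#' \eqn{E(\Delta Z \Delta W) = \tfrac{1}{2}\Delta t^2}. Components are
#' independent. Consumes the R RNG stream.
#'
#' @param n number of components.
#' @param dt step size, positive.
#' @return List with numeric vectors `dW` and `dZ` of length `n`.
#' @export
lca_increments <- function(n, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number")
  u1 <- stats::rnorm(n)
  u2 <- stats::rnorm(n)
  list(dW = u1 * sqrt(dt),
       dZ = 0.5 * dt^1.5 * (u1 + u2 / sqrt(3)))
}

#' One step of the strong order-1.5 Taylor scheme
#'
#' Advances the state by
#' \deqn{x_i' = x_i + a_i \Delta t + \xi \Delta W_i
#'   - \tfrac{1}{2}\{(\kappa - \beta) a_i + \beta \textstyle\sum_j a_j\}
#'     \Delta t^2
#'   - \xi \{(\kappa - \beta) \Delta Z_i + \beta \textstyle\sum_j \Delta Z_j\}}
#' with \eqn{a =} [lca_drift]. The noise being additive, no mixed diffusion
#' derivatives enter the scheme.
#'
#' @param params an [lca_params] object.
#' @param x numeric state vector of length N.
#' @param dt step size.
#' @param dW,dZ noise increments as from [lca_increments].
#' @return The next state, a numeric vector of length N.
#' @export
lca_step_taylor15 <- function(params, x, dt, dW, dZ) {
  a <- lca_drift(params, x)
  if (length(dW) != params$n || length(dZ) != params$n)
    stop("'dW' and 'dZ' must have length N")
  km <- params$kappa - params$beta
  x + a * dt + params$xi * dW -
    0.5 * (km * a + params$beta * sum(a)) * dt^2 -
    params$xi * (km * dZ + params$beta * sum(dZ))
}

#' Simulate log-evidence trajectories of the modified LCA model
#'
#' Generates `n_series` independent trajectories of the N-dimensional
#' log-evidence process on the uniform grid \eqn{t_k = k \Delta t}, using the
#' strong order-1.5 Taylor scheme (default) or plain Euler-Maruyama (for
#' cross-validation). One master seed deterministically spawns one child seed
#' per series; the child seeds are recorded so any single series can be
#' regenerated on its own.
#'
#' @param params an [lca_params] object.
#' @param n_steps points per series including the initial state (default
#'   20000).
#' @param dt step size \eqn{\Delta t} (default 0.01).
#' @param x0 initial log evidence: scalar (recycled across components, default
#'   -5, i.e. evidence \eqn{e^{-5} \approx 0.0067}, close to zero) or a vector
#'   of length N.
#' @param n_series number of independent series (default 128).
#' @param seed integer master seed; `NULL` leaves the RNG state as is.
#' @param series_seeds optional integer vector of length `n_series` giving the
#'   per-series seeds directly (e.g. to regenerate a single series from the
#'   `series_seeds` recorded in an earlier set); overrides `seed`-based
#'   spawning.
#' @param scheme `"taylor15"` (default) or `"euler"`.
#' @return An object of class `"lca_series"`: list with `times` (length
#'   `n_steps`), `states` (array `n_series` x `n_steps` x N), `params`, `dt`,
#'   `x0`, `scheme`, `seed` and `series_seeds`.
#' @examples
#' p <- lca_params(4, 1, c(0.9, 1.1), 0.25)
#' s <- lca_simulate(p, n_steps = 500, n_series = 2, seed = 1)
#' s
#' @export
lca_simulate <- function(params, n_steps = 20000L, dt = 0.01, x0 = -5,
                         n_series = 128L, seed = NULL, series_seeds = NULL,
                         scheme = c("taylor15", "euler")) {
  stopifnot(inherits(params, "lca_params"))
  scheme <- match.arg(scheme)
  n_steps <- as.integer(n_steps)
  n_series <- as.integer(n_series)
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be positive")
  if (n_steps < 2L) stop("'n_steps' must be at least 2")
  if (n_series < 1L) stop("'n_series' must be at least 1")
  if (length(x0) == 1L) x0 <- rep(as.numeric(x0), params$n)
  if (length(x0) != params$n)
    stop(sprintf("'x0' must be a scalar or have length N = %d", params$n))
  if (any(!is.finite(x0))) stop("'x0' must be finite")

  if (is.null(series_seeds)) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    series_seeds <- sample.int(.Machine$integer.max, n_series)
  } else {
    series_seeds <- as.integer(series_seeds)
    if (length(series_seeds) != n_series)
      stop("'series_seeds' must have length n_series")
  }

  states <- array(NA_real_, dim = c(n_series, n_steps, params$n))
  for (s in seq_len(n_series)) {
    set.seed(series_seeds[s])
    path <- tryCatch(
      simulate_path_cpp(n_steps, x0, dt, params$kappa, params$beta,
                        params$inputs, params$xi, scheme == "euler"),
      error = function(e) stop(sprintf("series %d: %s", s, conditionMessage(e)),
                               call. = FALSE)
    )
    states[s, , ] <- path
  }
  structure(
    list(times = (seq_len(n_steps) - 1) * dt, states = states,
         params = params, dt = dt, n_steps = n_steps, n_series = n_series,
         x0 = x0, scheme = scheme, seed = seed, series_seeds = series_seeds),
    class = "lca_series"
  )
}

#' Extract one trajectory from a series set
#'
#' @param series an `"lca_series"` object.
#' @param s series index.
#' @return An `n_steps` x N numeric matrix with columns `x1..xN`.
#' @export
series_matrix <- function(series, s = 1L) {
  stopifnot(inherits(series, "lca_series"))
  s <- as.integer(s)
  if (s < 1L || s > series$n_series) stop("series index out of range")
  m <- series$states[s, , , drop = TRUE]
  m <- matrix(m, nrow = series$n_steps)
  colnames(m) <- paste0("x", seq_len(ncol(m)))
  m
}

#' @export
print.lca_series <- function(x, ...) {
  cat(sprintf(
    "Modified LCA series set: %d series x %d points, N = %d, dt = %g, scheme = %s\n",
    x$n_series, x$n_steps, x$params$n, x$dt, x$scheme))
  if (!is.null(x$seed)) cat(sprintf("  master seed: %d\n", x$seed))
  tm <- series_matrix(x, 1L)
  cat("  series 1 terminal state:",
      paste(signif(tm[nrow(tm), ], 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.lca_series <- function(x, s = 1L, ...) {
  m <- series_matrix(x, s)
  graphics::matplot(x$times, m, type = "l", lty = 1,
                    xlab = "time", ylab = "log evidence x",
                    main = sprintf("Series %d of %d", s, x$n_series), ...)
  invisible(x)
}
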