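# Parameter-recovery study driver: simulate from known parameters, fit every
# series by maximum likelihood, and check that the truth is recovered.

# Reference calibration summaries for the three configurations — the recovery
# benchmarks this package is validated against (across 128 series of 20 000
# points each): calibrated mean, standard error, z-score per parameter. Kept
# with the case definitions as the single source of truth for tests and docs.
reference_rows <- function(name) {
  switch(name,
    N2 = list(
      calibrated = c(kappa = 4.01, beta = 0.97, I1 = 0.894, I2 = 1.095,
                     xi = 0.24998),
      se = c(kappa = 0.10, beta = 0.10, I1 = 0.026, I2 = 0.026, xi = 0.00089),
      z = c(kappa = 39.7, beta = 9.7, I1 = 33.9, I2 = 41.4, xi = 280.1)),
    N3 = list(
      calibrated = c(kappa = 3.963, beta = 0.998, I1 = 0.894, I2 = 1.094,
                     I3 = 0.978, xi = 0.24991),
      se = c(kappa = 0.088, beta = 0.051, I1 = 0.023, I2 = 0.023, I3 = 0.023,
             xi = 0.00073),
      z = c(kappa = 45.0, beta = 19.6, I1 = 38.8, I2 = 47.2, I3 = 42.9,
            xi = 342.5)),
    N10 = list(
      calibrated = c(kappa = 4.08, beta = 0.990, I1 = 0.898, I2 = 1.103,
                     I3 = 0.954, I4 = 1.199, I5 = 0.484, I6 = 0.741,
                     I7 = 0.796, I8 = 1.006, I9 = 1.008, I10 = 1.005,
                     xi = 0.25001),
      se = c(kappa = 0.17, beta = 0.020, I1 = 0.056, I2 = 0.057, I3 = 0.056,
             I4 = 0.058, I5 = 0.062, I6 = 0.057, I7 = 0.056, I8 = 0.056,
             I9 = 0.056, I10 = 0.056, xi = 0.00040),
      z = c(kappa = 24.3, beta = 48.9, I1 = 16.1, I2 = 19.4, I3 = 17.1,
            I4 = 20.6, I5 = 7.9, I6 = 13.0, I7 = 14.1, I8 = 17.9, I9 = 18.0,
            I10 = 17.9, xi = 631.6)),
    stop("unknown case name")
  )
}

#' Built-in parameter-recovery configurations
#'
#' The three reference configurations of the recovery study, all sharing
#' \eqn{\xi = 0.25}, \eqn{x_0 = -5}, \eqn{\Delta t = 0.01}, 20 000 points per
#' series and 128 series:
#' \itemize{
#'   \item `N2`: \eqn{\kappa = 4, \beta = 1, I = (0.9, 1.1)}
#'   \item `N3`: \eqn{\kappa = 4, \beta = 1, I = (0.9, 1.1, 0.98)}
#'   \item `N10`: \eqn{\kappa = 4, \beta = 1,
#'     I = (0.9, 1.1, 0.95, 1.2, 0.5, 0.75, 0.8, 1, 1, 1)}
#' }
#' Each case carries the reference calibrated-value / standard-error / z-score
#' rows for comparison.
#'
#' @param name optional: return just one case (`"N2"`, `"N3"`, `"N10"`).
#' @return A named list of `"lca_case"` objects (or a single one): each has
#'   `name`, `true_params` ([lca_params]), `n_steps`, `dt`, `x0`, `n_series`,
#'   and `expected` (list with `calibrated`, `se`, `z` vectors).
#' @examples
#' lca_cases("N2")$true_params
#' @export
lca_cases <- function(name = NULL) {
  make_case <- function(nm, params) {
    structure(list(name = nm, true_params = params, n_steps = 20000L,
                   dt = 0.01, x0 = -5, n_series = 128L,
                   expected = reference_rows(nm)),
              class = "lca_case")
  }
  cases <- list(
    N2 = make_case("N2", lca_params(4, 1, c(0.9, 1.1), 0.25)),
    N3 = make_case("N3", lca_params(4, 1, c(0.9, 1.1, 0.98), 0.25)),
    N10 = make_case("N10",
                    lca_params(4, 1, c(0.9, 1.1, 0.95, 1.2, 0.5,
                                       0.75, 0.8, 1, 1, 1), 0.25))
  )
  if (is.null(name)) cases
  else if (name %in% names(cases)) cases[[name]]
  else stop("unknown case: must be one of ", paste(names(cases), collapse = ", "))
}

#' @export
print.lca_case <- function(x, ...) {
  cat(sprintf("Recovery case %s: %d series x %d points, dt = %g, x0 = %g\n",
              x$name, x$n_series, x$n_steps, x$dt, x$x0))
  print(x$true_params)
  invisible(x)
}

#' Run a parameter-recovery study
#'
#' Simulates `n_series` independent log-evidence trajectories under the case's
#' true parameters, fits each one by maximum likelihood ([lca_fit]), and
#' aggregates the estimates into an exact / calibrated / standard-error /
#' z-score table. The whole run is reproducible from `seed` alone.
#'
#' @param case an `"lca_case"` (see [lca_cases]) or a case name.
#' @param n_series override the case's number of series (e.g. for a quick
#'   smoke run).
#' @param seed integer master seed for simulation.
#' @param init passed to [lca_fit] (default `"auto"`).
#' @param verbose print a one-line summary per fitted series.
#' @return An object of class `"lca_study"`: list with `case`, `aggregate`
#'   (an [lca_aggregate] result), `fits` (list of `"lca_fit"`), `table` (the
#'   rendered exact/calibrated/se/z matrix), `series_seeds`, `seed`, and
#'   `n_converged`. A warning is attached to the printout when more than 20%
#'   of fits failed to converge.
#' @examples
#' \donttest{
#' st <- lca_study("N2", n_series = 4, seed = 1)
#' st
#' }
#' @export
lca_study <- function(case, n_series = NULL, seed = NULL, init = "auto",
                      verbose = FALSE) {
  if (is.character(case)) case <- lca_cases(case)
  stopifnot(inherits(case, "lca_case"))
  if (case$true_params$xi <= 0) stop("degenerate case: xi must be positive")
  ns <- if (is.null(n_series)) case$n_series else as.integer(n_series)
  if (ns < 2L) stop("a study needs at least 2 series")

  sims <- lca_simulate(case$true_params, n_steps = case$n_steps, dt = case$dt,
                       x0 = case$x0, n_series = ns, seed = seed)
  fits <- vector("list", ns)
  for (s in seq_len(ns)) {
    fits[[s]] <- lca_fit(sims, s = s, init = init)
    if (verbose)
      message(sprintf("series %3d: loglik %.2f, %d restart(s), %s", s,
                      fits[[s]]$loglik, fits[[s]]$n_restarts,
                      if (fits[[s]]$converged) "converged" else "failed"))
  }
  agg <- lca_aggregate(fits)
  truth <- as.vector(case$true_params)
  tab <- rbind(`Exact value` = truth,
               `Calibrated value` = agg$table[, "mean"],
               `Standard error` = agg$table[, "se"],
               `z-score` = agg$table[, "z"])
  colnames(tab) <- names(truth)
  structure(
    list(case = case, aggregate = agg, fits = fits, table = tab,
         seed = seed, series_seeds = sims$series_seeds,
         n_converged = agg$n_converged, n_series = ns),
    class = "lca_study"
  )
}

#' @export
print.lca_study <- function(x, digits = 4, ...) {
  cat(sprintf("Parameter-recovery study, case %s (%d/%d fits converged)\n",
              x$case$name, x$n_converged, x$n_series))
  print(signif(x$table, digits))
  if (x$n_converged < 0.8 * x$n_series)
    cat("WARNING: more than 20% of fits failed to converge; ",
        "treat this summary with caution\n")
  invisible(x)
}

#' @export
summary.lca_study <- function(object, ...) {
  truth <- as.vector(object$case$true_params)
  dev <- (object$table["Calibrated value", ] - truth) /
    pmax(object$table["Standard error", ], .Machine$double.eps)
  structure(list(study = object, deviation_se = dev), class = "summary.lca_study")
}

#' @export
print.summary.lca_study <- function(x, ...) {
  print(x$study)
  cat("deviation of calibrated mean from truth, in SE units:\n")
  print(signif(x$deviation_se, 3))
  invisible(x)
}
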