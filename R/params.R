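#' Parameter set of the modified leaky competing accumulator model
#'
#' Bundles the parameters of the N-alternative modified LCA model, in which the
#' log-evidence \eqn{x_i = \ln y_i} of accumulator \eqn{i} follows
#' \deqn{dx_i = (I_i - \kappa x_i - \beta \sum_{j \ne i} x_j)\,dt + \xi\, dW_i.}
#' \eqn{\kappa} is the leakage (decay) rate, \eqn{\beta} the lateral-inhibition
#' rate (both 1/time), \eqn{I_i} the input to accumulator \eqn{i}, and
#' \eqn{\xi > 0} the diffusion coefficient. Working on the log scale keeps the
#' evidence \eqn{y_i = e^{x_i}} strictly positive (a stochastic Gompertz law).
#'
#' @param kappa leakage rate \eqn{\kappa} (scalar, finite).
#' @param beta inhibition rate \eqn{\beta} (scalar, finite).
#' @param inputs numeric vector of inputs \eqn{I_1, \dots, I_N}, length
#'   \eqn{N \ge 2}.
#' @param xi diffusion coefficient \eqn{\xi > 0}.
#' @return An object of class `"lca_params"`: a list with elements `kappa`,
#'   `beta`, `inputs`, `xi` and `n` (the number of alternatives).
#' @examples
#' p <- lca_params(kappa = 4, beta = 1, inputs = c(0.9, 1.1), xi = 0.25)
#' mean_input(p)
#' input_deviations(p)
#' @export
lca_params <- function(kappa, beta, inputs, xi) {
  inputs <- as.numeric(inputs)
  n <- length(inputs)
  if (n < 2L)
    stop("'inputs' must have length >= 2 (one input per alternative)")
  vals <- c(kappa, beta, inputs, xi)
  if (!is.numeric(vals) || any(!is.finite(vals)))
    stop("all model parameters must be finite numbers")
  if (xi <= 0)
    stop("'xi' must be strictly positive")
  structure(
    list(kappa = as.numeric(kappa), beta = as.numeric(beta),
         inputs = inputs, xi = as.numeric(xi), n = n),
    class = "lca_params"
  )
}

#' @rdname lca_params
#' @param params an `lca_params` object.
#' @export
mean_input <- function(params) {
  stopifnot(inherits(params, "lca_params"))
  mean(params$inputs)
}

#' @rdname lca_params
#' @details `input_deviations()` returns \eqn{\Delta I_i = I_i - \bar I}, which
#'   sum to zero; they drive the between-accumulator separation of the
#'   transition mean.
#' @export
input_deviations <- function(params) {
  stopifnot(inherits(params, "lca_params"))
  params$inputs - mean(params$inputs)
}

#' @export
print.lca_params <- function(x, ...) {
  cat(sprintf("Modified LCA parameters (N = %d alternatives)\n", x$n))
  cat(sprintf("  leakage kappa    : %g\n", x$kappa))
  cat(sprintf("  inhibition beta  : %g\n", x$beta))
  cat(sprintf("  inputs I         : %s\n", paste(signif(x$inputs, 6), collapse = ", ")))
  cat(sprintf("  diffusion xi     : %g\n", x$xi))
  invisible(x)
}

#' @export
as.vector.lca_params <- function(x, mode = "any") {
  c(kappa = x$kappa, beta = x$beta,
    stats::setNames(x$inputs, paste0("I", seq_len(x$n))), xi = x$xi)
}
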