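# Independent oracles used across the test files. Everything here is built
# from generic numerics (dense linear algebra, eigen decompositions, composite
# Simpson quadrature, the scalar OU closed form) and never calls the package's
# O(N) shortcut paths.

# Scalar OU process dx = (I - r x) dt + sigma dW: log transition density.
ou_log_density <- function(x, x0, tau, r, I, sigma) {
  m <- x0 * exp(-r * tau) + (I / r) * (1 - exp(-r * tau))
  v <- sigma^2 * (1 - exp(-2 * r * tau)) / (2 * r)
  stats::dnorm(x, mean = m, sd = sqrt(v), log = TRUE)
}

# Dense drift matrix of the coupled log-evidence process: dx = (I - A x) dt +
# xi dW with A = (kappa - beta) * diag(N) + beta * ones.
drift_matrix <- function(params) {
  n <- params$n
  (params$kappa - params$beta) * diag(n) + params$beta * matrix(1, n, n)
}

# Exact transition mean and covariance of the linear SDE, via the eigen
# decomposition of the (symmetric) drift matrix — no Wei-Norman coefficients.
ou_dense_moments <- function(params, x0, tau) {
  A <- drift_matrix(params)
  e <- eigen(A, symmetric = TRUE)
  V <- e$vectors
  lam <- e$values
  expm <- V %*% diag(exp(-lam * tau), params$n) %*% t(V)
  xstar <- solve(A, params$inputs)
  list(mean = as.numeric(xstar + expm %*% (x0 - xstar)),
       cov = V %*% diag(params$xi^2 * (1 - exp(-2 * lam * tau)) / (2 * lam),
                        params$n) %*% t(V))
}

# Dense multivariate Gaussian log density.
dense_gauss_log <- function(x, mean, Sigma) {
  d <- x - mean
  -0.5 * (length(x) * log(2 * pi) +
            as.numeric(determinant(Sigma, logarithm = TRUE)$modulus) +
            as.numeric(d %*% solve(Sigma, d)))
}

omega_dense <- function(b5, b6, n) b5 * diag(n) + b6 * matrix(1, n, n)

# Composite Simpson weights on a uniform grid of odd length.
simpson_weights <- function(n, h) {
  stopifnot(n %% 2 == 1)
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1; w[n] <- 1
  w * h / 3
}

params_n2 <- function() lca_params(4, 1, c(0.9, 1.1), 0.25)
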