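test_that("Wei-Norman coefficients match their closed forms and limits", {
  p <- params_n2()
  co <- wn_coefficients(p, 0.5)
  expect_equal(co$b3, -1.5)   # -(kappa - beta) * tau
  expect_equal(co$b4, -0.5)   # -beta * tau

  co0 <- wn_coefficients(p, 0)
  expect_equal(unlist(co0[paste0("b", 1:6)]), rep(0, 6),
               ignore_attr = TRUE)

  expect_equal(wn_coefficients(p, 1)$b1, (exp(3) - 1) / 3, tolerance = 1e-12)

  # kappa = beta: removable singularity handled by its analytic limit
  peq <- lca_params(2, 2, c(1, 1), 0.25)
  coeq <- wn_coefficients(peq, 0.7)
  expect_equal(coeq$b1, 0.7, tolerance = 1e-12)
  expect_equal(coeq$b5, 0.25^2 * 0.7 / 2, tolerance = 1e-12)

  # series branch agrees with the generic branch just outside the cutoff
  for (eps in c(1e-8, -1e-8)) {
    pn <- lca_params(2 + eps, 2, c(1, 1), 0.25)
    cn <- wn_coefficients(pn, 0.7)
    for (b in paste0("b", c(1, 2, 5, 6)))
      expect_equal(cn[[b]], coeq[[b]], tolerance = 1e-6)
  }

  # second singular direction: kappa + beta (N - 1) = 0
  psing <- lca_params(1, -1, c(0.2, 0.4), 0.3)
  pnear <- lca_params(1 + 1e-8, -1, c(0.2, 0.4), 0.3)
  cs <- wn_coefficients(psing, 0.4)
  cn <- wn_coefficients(pnear, 0.4)
  for (b in paste0("b", 1:6))
    expect_equal(cn[[b]], cs[[b]], tolerance = 1e-6)

  # coefficients vanish continuously as tau -> 0+
  ct <- wn_coefficients(p, 1e-10)
  expect_true(all(abs(unlist(ct[paste0("b", 1:6)])) < 1e-8))

  expect_error(wn_coefficients(p, -0.1), "non-negative")
  expect_error(wn_coefficients(p, NaN), "finite")
})

test_that("conditional mean reduces to known special cases", {
  p <- params_n2()
  x0 <- c(-5, -3)

  # zero lag: identity
  expect_equal(cond_mean(p, x0, 0), x0)

  # beta = 0: independent scalar OU means
  pb0 <- lca_params(4, 0, c(0.9, 1.1), 0.25)
  tau <- 0.3
  expect_equal(cond_mean(pb0, x0, tau),
               x0 * exp(-4 * tau) + (pb0$inputs / 4) * (1 - exp(-4 * tau)),
               tolerance = 1e-12)

  # permutation symmetry: equal starts and equal inputs give equal means
  psym <- lca_params(4, 1, c(1, 1, 1), 0.25)
  m <- cond_mean(psym, c(-5, -5, -5), 0.5)
  expect_equal(m, rep(m[1], 3))

  # general case against the dense matrix-exponential oracle
  for (p_t in list(params_n2(), lca_params(3, 0.7, c(0.5, 1, 1.5), 0.4))) {
    x0t <- seq(-2, 1, length.out = p_t$n)
    for (tau in c(0.05, 0.5, 2)) {
      mom <- ou_dense_moments(p_t, x0t, tau)
      expect_equal(cond_mean(p_t, x0t, tau), mom$mean, tolerance = 1e-10)
    }
  }

  expect_error(cond_mean(p, c(-5, -5, -5), 0.5), "length")
})

test_that("compound-symmetric inverse and determinant match dense algebra", {
  # diagonal case
  r <- omega_inverse_logdet(list(b5 = 0.3, b6 = 0), 4)
  expect_equal(r$inv_diag, 1 / 0.3)
  expect_equal(r$inv_off, 0)
  expect_equal(r$logdet, 4 * log(0.3))

  # 2x2 worked case
  r <- omega_inverse_logdet(list(b5 = 0.1, b6 = 0.05), 2)
  O <- omega_dense(0.1, 0.05, 2)
  expect_equal(exp(r$logdet), 0.1 * 0.2, tolerance = 1e-14)
  Oi <- (r$inv_diag - r$inv_off) * diag(2) + r$inv_off
  expect_equal(Oi, solve(O), tolerance = 1e-12, ignore_attr = TRUE)

  # random valid pairs, N = 2..6: reconstruction to 1e-12
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    b5 <- runif(1, 0.01, 2)
    b6 <- runif(1, -b5 / n * 0.9, 2)
    r <- omega_inverse_logdet(list(b5 = b5, b6 = b6), n)
    O <- omega_dense(b5, b6, n)
    Oi <- omega_dense(r$inv_diag - r$inv_off, r$inv_off, n)
    expect_lt(max(abs(O %*% Oi - diag(n))), 1e-12)
    expect_equal(r$logdet,
                 as.numeric(determinant(O, logarithm = TRUE)$modulus),
                 tolerance = 1e-12)
  }

  expect_error(omega_inverse_logdet(list(b5 = 0, b6 = 0.1), 3), "degenerate")
  expect_error(omega_inverse_logdet(list(b5 = 0.1, b6 = -0.05), 3),
               "degenerate")
})

test_that("joint log density agrees with Gaussian and OU oracles", {
  p <- params_n2()
  x0 <- c(-5, -5)
  tau <- 0.5

  # value at the mode
  co <- wn_coefficients(p, tau)
  om <- omega_inverse_logdet(co, 2)
  expect_equal(dlca(cond_mean(p, x0, tau), x0, tau, p),
               -log(4 * pi) - om$logdet / 2)

  # beta = 0: factorizes into independent scalar OU transitions
  pb0 <- lca_params(4, 0, c(0.9, 1.1), 0.25)
  set.seed(11)
  for (rep in 1:10) {
    x <- rnorm(2, -1, 1)
    x0r <- rnorm(2, -3, 1)
    expect_equal(dlca(x, x0r, 0.3, pb0),
                 ou_log_density(x[1], x0r[1], 0.3, 4, 0.9, 0.25) +
                   ou_log_density(x[2], x0r[2], 0.3, 4, 1.1, 0.25),
                 tolerance = 1e-10)
  }

  # general parameters against the dense Gaussian with eigen-oracle moments
  for (p_t in list(p, lca_params(3, 0.7, c(0.5, 1, 1.5), 0.4),
                   lca_params(1, 2, c(0.2, 0.5, 0.8, 1.1), 0.6))) {
    set.seed(23)
    x0t <- rnorm(p_t$n, -2, 1)
    xt <- rnorm(p_t$n, 0, 1)
    for (tau_t in c(0.05, 0.7)) {
      mom <- ou_dense_moments(p_t, x0t, tau_t)
      expect_equal(dlca(xt, x0t, tau_t, p_t),
                   dense_gauss_log(xt, mom$mean, mom$cov), tolerance = 1e-10)
    }
  }

  # permutation equivariance
  p3 <- lca_params(4, 1, c(0.9, 1.1, 0.98), 0.25)
  x0p <- c(-5, -4, -3); xp <- c(0.1, -0.2, 0.4)
  perm <- c(3, 1, 2)
  pp <- lca_params(4, 1, p3$inputs[perm], 0.25)
  expect_equal(dlca(xp, x0p, 0.5, p3),
               dlca(xp[perm], x0p[perm], 0.5, pp), tolerance = 1e-12)

  expect_error(dlca(c(0, 0), x0, 0, p), "positive")
  expect_error(dlca(c(0, 0), x0, -1, p), "positive")
})

test_that("joint density normalizes to 1 under 2-D quadrature", {
  p <- params_n2()
  x0 <- c(-5, -5)
  tau <- 0.5
  co <- wn_coefficients(p, tau)
  m <- cond_mean(p, x0, tau)
  sd1 <- sqrt(2 * (co$b5 + co$b6))
  ng <- 201
  g1 <- seq(m[1] - 8 * sd1, m[1] + 8 * sd1, length.out = ng)
  g2 <- seq(m[2] - 8 * sd1, m[2] + 8 * sd1, length.out = ng)
  w1 <- simpson_weights(ng, g1[2] - g1[1])
  w2 <- simpson_weights(ng, g2[2] - g2[1])
  vals <- outer(seq_len(ng), seq_len(ng),
                Vectorize(function(i, j) dlca(c(g1[i], g2[j]), x0, tau, p,
                                              log = FALSE)))
  expect_equal(as.numeric(w1 %*% vals %*% w2), 1, tolerance = 1e-6)
})

test_that("closed-form marginal equals numerical marginalization of the joint", {
  p <- params_n2()
  x0 <- c(-5, -4)
  tau <- 0.4
  co <- wn_coefficients(p, tau)
  m <- cond_mean(p, x0, tau)
  sdm <- sqrt(2 * (co$b5 + co$b6))

  # N = 2: integrate the joint over the other coordinate
  ng <- 401
  g2 <- seq(m[2] - 10 * sdm, m[2] + 10 * sdm, length.out = ng)
  w2 <- simpson_weights(ng, g2[2] - g2[1])
  for (x1 in m[1] + c(-1.5, 0, 0.8) * sdm) {
    num <- sum(w2 * vapply(g2, function(x2)
      dlca(c(x1, x2), x0, tau, p, log = FALSE), 0))
    expect_equal(dlca_marginal(x1, 1, x0, tau, p), num, tolerance = 1e-6)
  }

  # N = 3: 2-D marginalization
  p3 <- lca_params(4, 1, c(0.9, 1.1, 0.98), 0.25)
  x03 <- c(-5, -5, -5)
  co3 <- wn_coefficients(p3, tau)
  m3 <- cond_mean(p3, x03, tau)
  sd3 <- sqrt(2 * (co3$b5 + co3$b6))
  ng <- 121
  g2 <- seq(m3[2] - 9 * sd3, m3[2] + 9 * sd3, length.out = ng)
  g3 <- seq(m3[3] - 9 * sd3, m3[3] + 9 * sd3, length.out = ng)
  w2 <- simpson_weights(ng, g2[2] - g2[1])
  w3 <- simpson_weights(ng, g3[2] - g3[1])
  for (x1 in m3[1] + c(-1, 0.5) * sd3) {
    vals <- outer(seq_len(ng), seq_len(ng),
                  Vectorize(function(i, j)
                    dlca(c(x1, g2[i], g3[j]), x03, tau, p3, log = FALSE)))
    expect_equal(dlca_marginal(x1, 1, x03, tau, p3),
                 as.numeric(w2 %*% vals %*% w3), tolerance = 1e-6)
  }

  # marginal peak value and normalization up to N = 10
  for (p_t in list(p, lca_cases("N10")$true_params)) {
    cot <- wn_coefficients(p_t, tau)
    x0t <- rep(-5, p_t$n)
    mt <- cond_mean(p_t, x0t, tau)
    expect_equal(dlca_marginal(mt[2], 2, x0t, tau, p_t),
                 1 / sqrt(4 * pi * (cot$b5 + cot$b6)))
    sdt <- sqrt(2 * (cot$b5 + cot$b6))
    g <- seq(mt[1] - 10 * sdt, mt[1] + 10 * sdt, length.out = 801)
    w <- simpson_weights(801, g[2] - g[1])
    expect_equal(sum(w * dlca_marginal(g, 1, x0t, tau, p_t)), 1,
                 tolerance = 1e-6)
  }
})

test_that("two-alternative difference process is the expected scalar OU", {
  p <- params_n2()
  x0 <- c(-5, -4.2)
  for (tau in c(0.1, 0.5, 1.5)) {
    co <- wn_coefficients(p, tau)
    m <- cond_mean(p, x0, tau)
    a <- p$kappa - p$beta
    dI <- p$inputs[1] - p$inputs[2]
    # mean reverts at rate kappa - beta toward (I1 - I2)/(kappa - beta)
    expect_equal(m[1] - m[2],
                 (x0[1] - x0[2]) * exp(-a * tau) + dI / a * (1 - exp(-a * tau)),
                 tolerance = 1e-10)
    # Var(x1 - x2) = 4 b5: the OU with noise sqrt(2) xi
    expect_equal(4 * co$b5,
                 (sqrt(2) * p$xi)^2 * (1 - exp(-2 * a * tau)) / (2 * a),
                 tolerance = 1e-10)
  }
})

test_that("evidence transform is a positive-definite round trip", {
  expect_equal(evidence(0), 1)
  expect_equal(evidence(-5), exp(-5))
  expect_equal(evidence(-5), 0.00674, tolerance = 1e-3)
  set.seed(3)
  x <- rnorm(50)
  expect_equal(log_evidence(evidence(x)), x)
  y <- exp(rnorm(50))
  expect_equal(evidence(log_evidence(y)), y)
  expect_true(all(evidence(rnorm(50, -10, 5)) > 0))
  expect_error(log_evidence(c(1, 0)), "positive")
  expect_error(log_evidence(-2), "positive")
})
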