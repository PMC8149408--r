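# mlca — modified leaky competing accumulator models with exact likelihood

The leaky competing accumulator (LCA) is a standard model of decision making
among N alternatives: accumulator *i* gathers evidence with input *I*ᵢ, decays
at a leakage rate κ, and is inhibited at rate β by its competitors. In its
usual linear form the model has no known likelihood function (fitting is
simulation-based and slow), evidence is not guaranteed to stay positive, and
with two alternatives only the difference κ − β is identifiable.

`mlca` implements the *modified* LCA, in which each accumulator follows a
stochastic Gompertz growth law, so the log-evidence x = ln y obeys the coupled
Itô SDEs

    dxᵢ = (Iᵢ − κ xᵢ − β Σⱼ≠ᵢ xⱼ) dt + ξ dWᵢ,   i = 1..N.

This is a multivariate Ornstein–Uhlenbeck process whose lag-τ transition
density is an N-dimensional Gaussian available **in closed form**: its mean
and compound-symmetric covariance 2Ω (Ωᵢⱼ = b₅δᵢⱼ + b₆) are carried by six
Wei–Norman coefficients b₁(τ)…b₆(τ). With the exact transition density, the
likelihood of a discretely observed trajectory is an exact Markov product —
so maximum-likelihood calibration is fast, and κ and β are separately
identifiable even at N = 2.

The package provides:

* the closed-form density: `wn_coefficients()`, `cond_mean()`,
  `omega_inverse_logdet()` (O(N) Sherman–Morrison path), `dlca()`,
  `dlca_marginal()`, `evidence()` / `log_evidence()`;
* a strong order-1.5 Taylor Monte Carlo simulator `lca_simulate()` (plus an
  Euler–Maruyama cross-check scheme), with reproducible per-series seeding;
* exact-likelihood calibration `lca_fit()` by iterated Nelder–Mead (restart
  until the parameter change is below 10⁻⁶), with `print`, `summary`, `coef`,
  `logLik`, `predict`, `residuals`, `simulate` and `plot` methods;
* a parameter-recovery study driver `lca_study()` with the built-in two-,
  three- and ten-alternative reference configurations (`lca_cases()`);
* CSV + JSON-sidecar series I/O (`write_series()` / `read_series()`) and a
  command-line tool (`system.file("cli", "lca", package = "mlca")`) with
  `simulate`, `fit`, `recover` and `pdf` subcommands.

## Worked example

```r
library(mlca)

p   <- lca_params(kappa = 4, beta = 1, inputs = c(0.9, 1.1), xi = 0.25)
set <- lca_simulate(p, n_steps = 20000, dt = 0.01, x0 = -5,
                    n_series = 4, seed = 42)
fit <- lca_fit(set, s = 1)
fit
#> Modified LCA maximum-likelihood fit (N = 2, 19999 transitions)
#>    kappa     beta       I1       I2       xi
#> 4.115580 0.924292 0.915538 1.134640 0.251552
#> log-likelihood 91362.230; 4 optimizer run(s), converged
```

A single 200-time-unit series already pins down all five parameters: the
leakage and inhibition rates land near their true values (4 and 1) — not just
their difference — the inputs near (0.9, 1.1), and the diffusion coefficient
ξ within ~0.6% of 0.25. A miniature recovery study across 8 independent
series:

```r
st <- lca_study("N2", n_series = 8, seed = 7)
st
#> Parameter-recovery study, case N2 (8/8 fits converged)
#>                      kappa     beta        I1        I2        xi
#> Exact value        4.00000  1.00000 9.000e-01 1.100e+00 2.500e-01
#> Calibrated value   3.99500  1.03100 9.057e-01 1.100e+00 2.502e-01
#> Standard error     0.03563  0.04004 8.162e-03 9.418e-03 3.755e-04
#> z-score          112.10000 25.75000 1.110e+02 1.168e+02 6.662e+02
```

Rows: the generating ("exact") values, the across-series mean estimate, its
standard error (SD/√M), and the z-score mean/SE. Note ξ is recovered with by
far the smallest relative error — the diffusion scale is the best-identified
quantity in this model.

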