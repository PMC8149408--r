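---
title: "The modified LCA model: closed-form transition density, simulation and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The modified LCA model: closed-form transition density, simulation and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlca)
```

## The model

The leaky competing accumulator (LCA) is a neural-inspired model of decision
making among $N$ alternatives: accumulator $i$ gathers evidence driven by an
input $I_i$, loses activation at a leakage rate $\kappa$, and is suppressed by
lateral inhibition $\beta$ from the other accumulators. Its standard linear
form does not constrain evidence to stay positive, and — because the
two-alternative difference process is an Ornstein–Uhlenbeck (OU) diffusion
depending on $\kappa - \beta$ only — leakage and inhibition cannot be
calibrated separately from two-alternative data.

The modified model treated here resolves both problems at once by letting the
state variable be the *logarithm* of evidence, $x_i = \ln y_i$, so each
accumulator follows a stochastic Gompertz growth law and the evidence
$y_i = e^{x_i}$ is automatically positive. The log-evidence obeys the coupled
Itô SDEs

$$dx_i = \Big(I_i - \kappa x_i - \beta \sum_{j \ne i} x_j\Big)\,dt
       + \xi\, dW_i, \qquad i = 1, \dots, N,$$

a multivariate OU process with compound-symmetric drift matrix
$A = (\kappa - \beta)\mathbb{1} + \beta J$ ($J$ the all-ones matrix) and
additive, uncorrelated noise. Independence of the $dW_i$ across accumulators
is the standard Wiener assumption for this model; nothing in the drift couples
the noise.

## Closed-form transition density

The lag-$\tau$ transition density is an $N$-dimensional Gaussian whose
parameters are carried by six scalar coefficients obtained from a Wei–Norman
(Lie-algebraic) disentangling of the backward Kolmogorov evolution operator.
With $a = \kappa - \beta$ and $m = \kappa + \beta(N-1)$ (the two eigenvalues
of $A$):

$$b_1 = \frac{e^{a\tau}-1}{a},\quad
  b_2 = \bar I\,\frac{e^{m\tau}-1}{m},\quad
  b_3 = -a\tau,\quad b_4 = -\beta\tau,$$
$$b_5 = \frac{\xi^2}{4a}\big(1 - e^{-2a\tau}\big),\quad
  b_6 = \frac{\xi^2}{4N}\left(\frac{1-e^{-2m\tau}}{m}
        - \frac{1-e^{-2a\tau}}{a}\right),$$

where $\bar I$ is the mean input. The density is

$$P(x \mid x_0, \tau)
  = \frac{1}{\sqrt{(4\pi)^N \det\Omega}}
    \exp\Big\{-\tfrac14 (X_0 - x)^\top \Omega^{-1} (X_0 - x)\Big\},
  \qquad \Omega_{ij} = b_5\,\delta_{ij} + b_6,$$

i.e. a Gaussian with mean $X_0$ (`cond_mean()`) and covariance $2\Omega$ —
note the $\tfrac14$ in the quadratic form, which fixes the covariance
convention used consistently by every oracle and moment in this package. The
marginal for a single accumulator is the scalar Gaussian with variance
$2(b_5 + b_6)$ (`dlca_marginal()`).

Numerical choices, all made once:

* **Removable singularities.** $b_1, b_2, b_5, b_6$ are built from
  $(e^{a\tau}-1)/a$-type factors that are $0/0$ at $a = 0$ ($\kappa = \beta$)
  or $m = 0$. Below $|a| < 10^{-6}$ the factor switches to its third-order
  series $\tau(1 + z/2 + z^2/6 + z^3/24)$, $z = a\tau$, keeping every
  coefficient continuous in the parameters — important because the optimizer
  freely crosses $\kappa = \beta$.
* **O(N) density path.** $\Omega$ is compound-symmetric, so
  $\Omega^{-1} = \tfrac1{b_5}\big(\mathbb{1} - \tfrac{b_6}{b_5 + N b_6}J\big)$
  and $\det\Omega = b_5^{N-1}(b_5 + N b_6)$; the $N \times N$ matrix is never
  materialized and all density work stays in log space. A likelihood pass over
  a 20&nbsp;000-point series costs $O(TN)$.
* **No stationarity restriction.** The coefficients are valid for any real
  $\kappa, \beta$ at finite $\tau$; only positive definiteness of $2\Omega$ is
  enforced (it holds automatically for $\tau > 0$). At $\tau = 0$ the density
  degenerates to a product of delta functions, reported as an error rather
  than a special object — no consumer needs the delta.

## Simulation

`lca_simulate()` integrates the SDEs with the strong order-1.5 Taylor scheme:

$$x_i^{t+\Delta t} = x_i^t + a_i \Delta t + \xi \Delta W_i
  - \tfrac12\big\{(\kappa-\beta)a_i + \beta {\textstyle\sum_j} a_j\big\}\Delta t^2
  - \xi\big\{(\kappa-\beta)\Delta Z_i + \beta {\textstyle\sum_j} \Delta Z_j\big\},$$

with $\Delta W_i = U_{i,1}\sqrt{\Delta t}$ and
$\Delta Z_i = \tfrac12 \Delta t^{3/2}(U_{i,1} + U_{i,2}/\sqrt3)$, so that
$E(\Delta Z_i^2) = \tfrac13\Delta t^3$ and
$E(\Delta Z_i \Delta W_i) = \tfrac12\Delta t^2$. The noise being additive, no
mixed diffusion derivatives arise. A plain Euler–Maruyama scheme is kept as a
cross-validation oracle (`scheme = "euler"`); its mean bias is first order in
$\Delta t$, so the scheme-agreement test in the suite runs at
$\Delta t = 10^{-3}$, where that bias sits below Monte-Carlo resolution.

Seeding: one master seed deterministically spawns one child seed per series;
child seeds are recorded in the returned object so any single series can be
regenerated alone (`series_seeds =`). A series is aborted with an error if any
$|x|$ exceeds $10^3$ — unstable $(\kappa, \beta)$ regions must fail loudly,
not return infinities.

The default configuration — $x_i(0) = -5$ for every accumulator (evidence
$e^{-5} \approx 0.0067$, i.e. "almost zero" on the natural scale),
$\Delta t = 0.01$, 20&nbsp;000 points per series, 128 series — is the
reference protocol replicated by the recovery study; these are study
conditions, not tuning knobs.

## Likelihood and calibration

Because the one-step transition density is exact, the likelihood of a series
observed on a uniform grid is the exact Markov product
$\ell(\theta) = \sum_k \log P(x^{(k+1)} \mid x^{(k)}, \Delta t)$ — no
discretization approximation enters the inference. This is the only
construction consistent with a discretely observed diffusion whose transition
law is known in closed form.

`lca_fit()` maximizes $\ell$ over $(\kappa, \beta, I_1, \dots, I_N, \log\xi)$
with Nelder–Mead ($\xi$ on the log scale to enforce positivity; everything
else unconstrained). The simplex search is *iterated*: each run's solution
seeds the next run, until the largest absolute parameter change between
successive runs drops below $10^{-6}$ (the `restart_tol`), with a cap of 50
runs (then `converged = FALSE`, never an exception). Inner runs use
`reltol = 1e-8` and `maxit = 200` per free parameter. Restarting a collapsed
simplex from its own optimum is the standard cure for Nelder–Mead's tendency
to stall on flat ridges, and the $10^{-6}$ rule makes "the optimizer has
stopped moving" a precise, parameterization-independent statement.

Starting values (`init = "auto"`) come from per-component lag-1
autoregressions: the pooled slope gives an effective reversion rate used as
the $\kappa - \beta$ start, residual variance gives $\xi$, the implied
long-run means give the inputs through the drift fixed point, and $\beta$
starts at half the $\kappa-\beta$ scale. Nothing about the generating
parameters is used, and the choice is documented so users can override it.
Degenerate (constant) series are refused at initialization with advice to
supply an explicit start; with an explicit start they run to a flagged
non-convergence or a $\hat\xi \to 0$ boundary rather than crashing.

`lca_aggregate()` summarizes $M$ per-series fits by the across-series mean,
the standard error of that mean (sample SD divided by $\sqrt M$) and the
z-score mean/SE. Identical estimates yield SE $= 0$ and an infinite z marker.
Fits are independent across series, so sequential and parallel execution give
identical results; the package runs them sequentially.

## The recovery study

`lca_cases()` ships three reference configurations (two, three and ten
alternatives; all with $\kappa = 4$, $\beta = 1$, $\xi = 0.25$ and inputs
spread around 1), together with reference calibration summaries for
comparison. `lca_study()` simulates, fits every series, and renders an
Exact / Calibrated / Standard error / z-score table; it warns when more than
20% of fits fail to converge. The study driver defaults to `init = "auto"`
and records the per-series seeds, so a study is reproducible from its master
seed alone.

Problem sizes used by the shipped validation suite and the acceptance script:
the two- and three-alternative studies run at the full 128 series of
20&nbsp;000 points; the ten-alternative study runs at 32 series, which
inflates across-series standard errors by about a factor of two and is
accounted for in the comparison bands. The simulator/density cross-check uses
$10^4$ trajectories at lag $0.5$. These sizes were chosen once as the
smallest runs that leave Monte-Carlo error well inside the comparison bands.

## What the synthetic data does and does not show

All validation in this package is against data generated by its own
simulator, under the model's exact assumptions: linear drift, additive
Gaussian noise, uncorrelated accumulators, constant parameters, uniform
sampling. Passing the recovery study therefore demonstrates *internal*
correctness — the density, simulator and optimizer agree, and the estimator
is unbiased and tight at these sample sizes. It does not show that real
choice or neural data follow a stochastic Gompertz law, that parameters are
stable over a session, or that the model is identifiable from the much
shorter, threshold-censored trajectories behavioural experiments yield (this
package deliberately implements no decision threshold or reaction-time
readout). Misspecification robustness — e.g. fitting this model to data from
the unmodified linear LCA — is likewise out of scope.

## Known limitations

* Standard errors come from across-series dispersion only; no
  observed-information (Hessian) errors for a single series.
* Time-varying parameters are not supported, although the underlying
  Lie-algebraic construction extends to them.
* The exact likelihood requires uniform sampling; irregular grids would need
  per-step coefficient recomputation (straightforward but not implemented).
* Nelder–Mead is derivative-free and robust here, but for $N \gg 10$ a
  gradient-based optimizer on the closed-form likelihood would scale better.
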