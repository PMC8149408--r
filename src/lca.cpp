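#include <Rcpp.h>
using namespace Rcpp;

// Sum of one-step Gaussian transition log-densities over a uniformly sampled
// series. The transition at lag dt is N(mean, 2*Omega) with compound-symmetric
// Omega; all lag-dependent quantities are precomputed once by the caller:
//   b1dI     : b1 * DeltaI_i                     (length N)
//   b2eNb4   : b2 * exp(N*b4)                    (scalar)
//   cj       : (exp(N*b4) - 1) / N               (scalar)
//   eb3      : exp(b3)                           (scalar)
//   inv_diag : diagonal of Omega^{-1}
//   inv_off  : off-diagonal of Omega^{-1}
//   logdet   : log det Omega
// The quadratic form uses d' Omega^{-1} d = (inv_diag - inv_off) * sum(d_i^2)
// + inv_off * (sum d_i)^2, valid for any compound-symmetric inverse.
// [[Rcpp::export]]
double loglik_sum_cpp(const NumericMatrix& x, const NumericVector& b1dI,
                      double b2eNb4, double cj, double eb3,
                      double inv_diag, double inv_off, double logdet) {
  const int T = x.nrow();
  const int N = x.ncol();
  const double const_term = -0.5 * N * std::log(4.0 * M_PI) - 0.5 * logdet;
  const double a = inv_diag - inv_off;
  // column-major passes with sequential access: row sums first, then the
  // per-component innovations accumulated into per-step sums
  std::vector<double> srow(T, 0.0), q(T - 1, 0.0), sd(T - 1, 0.0);
  const double* xp = REAL(x);
  for (int i = 0; i < N; ++i) {
    const double* col = xp + (size_t)i * T;
    for (int k = 0; k < T; ++k) srow[k] += col[k];
  }
  for (int i = 0; i < N; ++i) {
    const double* col = xp + (size_t)i * T;
    const double shift = b2eNb4 + b1dI[i];
    for (int k = 0; k + 1 < T; ++k) {
      double d = (col[k] + shift + cj * srow[k]) * eb3 - col[k + 1];
      q[k] += d * d;
      sd[k] += d;
    }
  }
  double ll = (double)(T - 1) * const_term;
  for (int k = 0; k + 1 < T; ++k)
    ll -= 0.25 * (a * q[k] + inv_off * sd[k] * sd[k]);
  return ll;
}

// Strong order-1.5 Taylor (or Euler-Maruyama) integration of the coupled
// log-evidence SDEs dx_i = (I_i - kappa x_i - beta sum_{j!=i} x_j) dt + xi dW_i.
// Returns an n_steps x N matrix whose first row is x0. Uses R's RNG so a
// set.seed() call in the caller makes the path reproducible.
// [[Rcpp::export]]
NumericMatrix simulate_path_cpp(int n_steps, const NumericVector& x0, double dt,
                                double kappa, double beta, const NumericVector& I,
                                double xi, bool euler) {
  const int N = x0.size();
  const double km = kappa - beta;
  const double sqdt = std::sqrt(dt);
  const double zc = 0.5 * dt * sqdt;           // 0.5 * dt^{3/2}
  const double is3 = 1.0 / std::sqrt(3.0);
  NumericMatrix out(n_steps, N);
  std::vector<double> x(N), a(N), dW(N), dZ(N);
  for (int i = 0; i < N; ++i) { x[i] = x0[i]; out(0, i) = x0[i]; }
  for (int k = 1; k < n_steps; ++k) {
    double sx = 0.0;
    for (int i = 0; i < N; ++i) sx += x[i];
    double sa = 0.0;
    for (int i = 0; i < N; ++i) {
      a[i] = I[i] - km * x[i] - beta * sx;
      sa += a[i];
    }
    double sz = 0.0;
    for (int i = 0; i < N; ++i) {
      double u1 = norm_rand();
      double u2 = norm_rand();
      dW[i] = u1 * sqdt;
      dZ[i] = zc * (u1 + is3 * u2);
      sz += dZ[i];
    }
    for (int i = 0; i < N; ++i) {
      double xn = x[i] + a[i] * dt + xi * dW[i];
      if (!euler)
        xn += -0.5 * (km * a[i] + beta * sa) * dt * dt
              - xi * (km * dZ[i] + beta * sz);
      x[i] = xn;
      out(k, i) = xn;
      if (!(std::fabs(xn) <= 1.0e3))
        stop("simulation diverged at step %d, component %d (|x| > 1e3)", k, i + 1);
    }
  }
  return out;
}
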