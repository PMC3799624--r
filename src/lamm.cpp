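#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Bernoulli function x / (exp(x) - 1), series near 0 to avoid cancellation.
static inline double bernoulli_fn(double x) {
  if (std::fabs(x) < 1e-8) return 1.0 - x / 2.0 + x * x / 12.0;
  return x / std::expm1(x);
}

//' @title Finite-volume Crank-Nicolson march of the Lamm equation (internal)
//' @description Solves d(chi)/dt = (1/r) d/dr [ r D dchi/dr - s w^2 r^2 chi ]
//'   on a uniform grid spanning the solution column, with zero-flux (reflecting)
//'   boundaries at both ends. Fluxes are exponentially fitted
//'   (Scharfetter-Gummel), so the scheme stays stable and non-oscillatory from
//'   diffusion-dominated to advection-dominated regimes and conserves total
//'   mass to rounding error. Called from solve_lamm(); not user-facing.
//' @param r uniform radial grid, cm
//' @param s_sec sedimentation coefficient in seconds
//' @param D diffusion coefficient, cm^2/s
//' @param omega2 squared angular velocity, rad^2/s^2
//' @param c0 uniform loading concentration
//' @param t_out ascending output times, s (effective constant-omega time)
//' @param courant advective Courant-number cap per substep
//' @return matrix length(r) x length(t_out)
//' @keywords internal
// [[Rcpp::export(name = ".lamm_march")]]
NumericMatrix lamm_march(NumericVector r, double s_sec, double D, double omega2,
                         double c0, NumericVector t_out, double courant = 1.0) {
  const int N = r.size(), M = t_out.size();
  if (N < 3) stop("internal grid must have at least 3 points");
  const double h = r[1] - r[0];

  // sector-cell control volumes (per unit angle/thickness): V_j = integral r dr
  std::vector<double> V(N);
  for (int j = 0; j < N; ++j) V[j] = r[j] * h;
  V[0] = (r[0] + h / 4.0) * h / 2.0;
  V[N - 1] = (r[N - 1] - h / 4.0) * h / 2.0;

  // face fluxes F_{j+1/2} = fa[j]*chi_j + fb[j]*chi_{j+1} (positive toward bottom)
  std::vector<double> fa(N - 1), fb(N - 1);
  for (int j = 0; j < N - 1; ++j) {
    const double rf = 0.5 * (r[j] + r[j + 1]);
    const double v = s_sec * omega2 * rf;
    if (D > 0.0) {
      const double P = v * h / D;
      fa[j] = rf * (D / h) * bernoulli_fn(-P);
      fb[j] = -rf * (D / h) * bernoulli_fn(P);
    } else { // pure advection: upwind
      if (v >= 0.0) { fa[j] = rf * v; fb[j] = 0.0; }
      else          { fa[j] = 0.0;    fb[j] = rf * v; }
    }
  }

  // tridiagonal generator A: V_j dchi_j/dt = F_{j-1/2} - F_{j+1/2}
  std::vector<double> Al(N, 0.0), Ad(N, 0.0), Au(N, 0.0);
  for (int j = 0; j < N; ++j) {
    if (j > 0)     { Al[j] += fa[j - 1] / V[j]; Ad[j] += fb[j - 1] / V[j]; }
    if (j < N - 1) { Ad[j] -= fa[j] / V[j];     Au[j] -= fb[j] / V[j]; }
  }

  std::vector<double> chi(N, c0), d(N), dp(N);
  // Thomas factorization of (I - dt/2 A), reused while dt is unchanged
  std::vector<double> cp(N), inv_den(N), low(N);
  double dt_fact = -1.0;
  NumericMatrix out(N, M);
  double tc = 0.0;
  const double vmax = std::fabs(s_sec) * omega2 * r[N - 1];
  const bool capped = vmax > 0.0;
  const double dtmax = capped ? courant * h / vmax : 0.0;

  for (int mi = 0; mi < M; ++mi) {
    const double T = t_out[mi];
    if (T > tc) {
      int nsub = 1;
      if (capped) {
        nsub = (int)std::ceil((T - tc) / dtmax);
        if (nsub < 1) nsub = 1;
      }
      const double dt = (T - tc) / nsub;
      if (dt != dt_fact) {  // refactor the implicit operator
        double b0 = 1.0 - 0.5 * dt * Ad[0];
        cp[0] = (-0.5 * dt * Au[0]) / b0;
        inv_den[0] = 1.0 / b0;
        low[0] = 0.0;
        for (int j = 1; j < N; ++j) {
          const double aj = -0.5 * dt * Al[j];
          const double bj = 1.0 - 0.5 * dt * Ad[j];
          const double cj = (j < N - 1) ? (-0.5 * dt * Au[j]) : 0.0;
          const double den = bj - aj * cp[j - 1];
          cp[j] = cj / den;
          inv_den[j] = 1.0 / den;
          low[j] = aj;
        }
        dt_fact = dt;
      }
      for (int k = 0; k < nsub; ++k) {
        // RHS: (I + dt/2 A) chi
        d[0] = chi[0] + 0.5 * dt * (Ad[0] * chi[0] + Au[0] * chi[1]);
        for (int j = 1; j < N - 1; ++j)
          d[j] = chi[j] + 0.5 * dt * (Al[j] * chi[j - 1] + Ad[j] * chi[j] +
                                      Au[j] * chi[j + 1]);
        d[N - 1] = chi[N - 1] + 0.5 * dt * (Al[N - 1] * chi[N - 2] +
                                            Ad[N - 1] * chi[N - 1]);
        // forward/back substitution with the cached factorization
        dp[0] = d[0] * inv_den[0];
        for (int j = 1; j < N; ++j)
          dp[j] = (d[j] - low[j] * dp[j - 1]) * inv_den[j];
        chi[N - 1] = dp[N - 1];
        for (int j = N - 2; j >= 0; --j) chi[j] = dp[j] - cp[j] * chi[j + 1];
      }
      tc = T;
    }
    for (int j = 0; j < N; ++j) out(j, mi) = chi[j];
  }
  return out;
}
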