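#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Six-state rate vector at one state. Parameter order:
// V_p, K_b, h, K_ma, V_q, V_r, k_d1, k_d2, k_a, t_lag.
// State order: P, A, B, Q, R, E. The enzyme lag branch is handled by the
// caller (lag_active flag) so the integration grid can be split exactly
// at t_lag.
static inline void rates(const double* par, const double* y, double Ph_b,
                         bool lag_active, double* dy) {
  const double P = y[0], A = y[1], B = y[2], Q = y[3], E = y[5];
  (void)P;
  double kb = 0.0;
  if (B > 0.0) kb = par[1] * std::pow(B, par[2]);
  const double dP = par[0] * (kb / (1.0 + kb)) * (A / (par[3] + A)) * E;
  const double dQ = par[4] * A * E - par[5] * A * Q * E;
  const double dR = par[5] * A * Q * E;
  dy[0] = dP;
  dy[1] = -dP - dQ - 2.0 * dR;
  dy[2] = -dP;
  dy[3] = dQ;
  dy[4] = dR;
  dy[5] = lag_active ? (-(par[6] + par[7] * B) * E + par[8] * Ph_b) : 0.0;
}

// Build the integration grid: multiples of `step` up to t_end, with an
// extra node at t_lag so the deactivation branch switches exactly there.
static std::vector<double> build_grid(double step, double t_end, double t_lag) {
  const int n = (int)std::lround(t_end / step);
  std::vector<double> g;
  g.reserve(n + 2);
  for (int i = 0; i <= n; ++i) g.push_back(i * step);
  if (t_lag > 0.0 && t_lag < t_end) {
    bool on = false;
    for (double t : g)
      if (std::fabs(t - t_lag) < 1e-9) { on = true; break; }
    if (!on) {
      g.push_back(t_lag);
      std::sort(g.begin(), g.end());
    }
  }
  return g;
}

// Explicit-Euler integration. Returns the full trajectory (one row per
// grid node) together with the worst clamping magnitude (negative
// overshoot reset to zero) and the worst linear-conservation drift.
// [[Rcpp::export(name = ".euler_core")]]
List euler_core(NumericVector params, NumericVector y0, double Ph_b,
                double t_end, double step) {
  const double* par = REAL(params);
  const double t_lag = par[9];
  std::vector<double> grid = build_grid(step, t_end, t_lag);
  const int m = (int)grid.size();
  NumericMatrix out(m, 7);
  double y[6], dy[6];
  for (int j = 0; j < 6; ++j) y[j] = y0[j];
  out(0, 0) = grid[0];
  for (int j = 0; j < 6; ++j) out(0, j + 1) = y[j];
  double max_clamp = 0.0;
  for (int i = 0; i + 1 < m; ++i) {
    const double t = grid[i], h = grid[i + 1] - grid[i];
    rates(par, y, Ph_b, t >= t_lag - 1e-12, dy);
    for (int j = 0; j < 6; ++j) {
      y[j] += h * dy[j];
      if (y[j] < 0.0) {
        if (-y[j] > max_clamp) max_clamp = -y[j];
        y[j] = 0.0;
      }
    }
    out(i + 1, 0) = grid[i + 1];
    for (int j = 0; j < 6; ++j) out(i + 1, j + 1) = y[j];
  }
  return List::create(_["trajectory"] = out, _["max_clamp"] = max_clamp);
}

// Euler integration reporting only the states at multiples of `interval`
// (including t = 0). Used by the fitting objective.
static void euler_sampled(const double* par, const double* y0, double Ph_b,
                          double t_end, double step, double interval,
                          double* out /* n_samp x 6, column-major */,
                          int n_samp) {
  const double t_lag = par[9];
  std::vector<double> grid = build_grid(step, t_end, t_lag);
  const int m = (int)grid.size();
  double y[6], dy[6];
  for (int j = 0; j < 6; ++j) y[j] = y0[j];
  for (int j = 0; j < 6; ++j) out[0 + j * n_samp] = y[j];
  for (int i = 0; i + 1 < m; ++i) {
    const double t = grid[i], h = grid[i + 1] - grid[i];
    rates(par, y, Ph_b, t >= t_lag - 1e-12, dy);
    for (int j = 0; j < 6; ++j) {
      y[j] += h * dy[j];
      if (y[j] < 0.0) y[j] = 0.0;
    }
    const double tt = grid[i + 1];
    const double k = tt / interval;
    const long kk = std::lround(k);
    if (std::fabs(tt - kk * interval) < 1e-9 && kk >= 1 && kk < n_samp) {
      for (int j = 0; j < 6; ++j) out[kk + j * n_samp] = y[j];
    }
  }
}

// Sampled simulation exposed to R: rows at 0, interval, 2*interval, ...
// [[Rcpp::export(name = ".euler_sampled")]]
NumericMatrix euler_sampled_r(NumericVector params, NumericVector y0,
                              double Ph_b, double t_end, double step,
                              double interval) {
  const int n_samp = (int)std::lround(t_end / interval) + 1;
  NumericMatrix out(n_samp, 6);
  euler_sampled(REAL(params), REAL(y0), Ph_b, t_end, step, interval,
                REAL(out), n_samp);
  return out;
}

// Total residual sum of squares of one parameter vector against a set of
// observed profiles. `obs` is a list of numeric matrices (n_samp x 6,
// columns P, A, B, Q, R, E), `y0s` the matching list of initial states,
// `Ph_b`, `t_end`, `interval` per profile. `include_P` switches the PAC
// component in and out of the total.
// [[Rcpp::export(name = ".rss_total_core")]]
double rss_total_core(NumericVector params, List obs, List y0s,
                      NumericVector Ph_b, NumericVector t_end,
                      NumericVector interval, double step, bool include_P) {
  const int np = obs.size();
  double total = 0.0;
  std::vector<double> sim;
  for (int i = 0; i < np; ++i) {
    NumericMatrix ob = obs[i];
    NumericVector y0 = y0s[i];
    const int n_samp = ob.nrow();
    sim.assign((size_t)n_samp * 6, 0.0);
    euler_sampled(REAL(params), REAL(y0), Ph_b[i], t_end[i], step,
                  interval[i], sim.data(), n_samp);
    for (int j = 0; j < 6; ++j) {
      if (j == 0 && !include_P) continue;
      for (int k = 0; k < n_samp; ++k) {
        const double r = ob(k, j) - sim[k + (size_t)j * n_samp];
        total += r * r;
      }
    }
  }
  return total;
}
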