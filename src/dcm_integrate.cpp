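// Fixed-step RK4 integration of the one-state-per-region nonlinear DCM
// neural equation coupled to balloon hemodynamics, with BOLD sampled every
// `sample_every` steps. Inputs are zero-order-held over each step, so a
// reference run at a finer step that subdivides the grid sees identical
// input timing.
//
// Neural:   dx/dt = (A + sum_j u_j B_j + sum_k x_k D_k) x + C u
// Hemo per region (s: vasodilatory signal, f: inflow, v: volume, q: dHb):
//   ds/dt = x - kappa s - gamma (f - 1)
//   df/dt = s
//   tau dv/dt = f - v^(1/alpha)
//   tau dq/dt = f (1 - (1-E0)^(1/f)) / E0 - v^(1/alpha) q / v
// BOLD = V0 (k1 (1-q) + k2 (1-q/v) + k3 (1-v)),
//   k1 = 7 E0, k2 = 2, k3 = 2 E0 - 0.2.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

struct SparseEntry { int i, j, k; double val; };

static inline bool deriv(const std::vector<double>& Aflat, int n,
                         const std::vector<SparseEntry>& Bnz,
                         const std::vector<SparseEntry>& Dnz,
                         const std::vector<double>& Cflat, int m,
                         const double* u,
                         const double* x, const double* s,
                         const double* f, const double* v, const double* q,
                         const double* tau, double kappa, double gamma,
                         double inv_alpha, double E0, double log1mE0,
                         double* dx, double* ds, double* df,
                         double* dv, double* dq,
                         std::vector<double>& M) {
  // effective connectivity for the current inputs and states
  std::copy(Aflat.begin(), Aflat.end(), M.begin());
  for (size_t e = 0; e < Bnz.size(); ++e)
    M[Bnz[e].i * n + Bnz[e].j] += u[Bnz[e].k] * Bnz[e].val;
  for (size_t e = 0; e < Dnz.size(); ++e)
    M[Dnz[e].i * n + Dnz[e].j] += x[Dnz[e].k] * Dnz[e].val;
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    const double* Mi = &M[i * n];
    for (int j = 0; j < n; ++j) acc += Mi[j] * x[j];
    for (int k = 0; k < m; ++k) acc += Cflat[i * m + k] * u[k];
    dx[i] = acc;
  }
  for (int i = 0; i < n; ++i) {
    if (!(v[i] > 1e-8) || !(q[i] > 1e-8) || !(f[i] > 1e-8)) return false;
    ds[i] = x[i] - kappa * s[i] - gamma * (f[i] - 1.0);
    df[i] = s[i];
    double v_a = std::exp(std::log(v[i]) * inv_alpha);  // v^(1/alpha)
    double extraction = (1.0 - std::exp(log1mE0 / f[i])) / E0;
    dv[i] = (f[i] - v_a) / tau[i];
    dq[i] = (f[i] * extraction - v_a * q[i] / v[i]) / tau[i];
  }
  return true;
}

// [[Rcpp::export]]
List dcm_integrate_cpp(NumericMatrix A, NumericVector Barr,
                       NumericMatrix C, NumericVector Darr,
                       NumericMatrix U, double dt, int sample_every,
                       NumericVector tau, double kappa, double gamma,
                       double alpha, double E0, double V0) {
  const int n = A.nrow();
  const int m = C.ncol();
  const int n_steps = U.nrow();
  if (U.ncol() != m) stop("input matrix has %d columns, expected %d",
                          U.ncol(), m);
  if ((int) tau.size() != n) stop("tau must have one entry per region");
  const int n_samples = n_steps / sample_every;

  std::vector<double> Aflat(n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) Aflat[i * n + j] = A(i, j);
  std::vector<double> Cflat(n * m);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < m; ++k) Cflat[i * m + k] = C(i, k);

  std::vector<SparseEntry> Bnz, Dnz;
  IntegerVector bdim = Barr.attr("dim");
  if (bdim.size() != 3 || bdim[0] != n || bdim[1] != n || bdim[2] != m)
    stop("B array must be n x n x n_inputs");
  for (int k = 0; k < m; ++k)
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) {
        double val = Barr[k * n * n + j * n + i];
        if (val != 0.0) Bnz.push_back({i, j, k, val});
      }
  IntegerVector ddim = Darr.attr("dim");
  if (ddim.size() != 3 || ddim[0] != n || ddim[1] != n || ddim[2] != n)
    stop("D array must be n x n x n_regions");
  for (int k = 0; k < n; ++k)
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) {
        double val = Darr[k * n * n + j * n + i];
        if (val != 0.0) Dnz.push_back({i, j, k, val});
      }

  const double inv_alpha = 1.0 / alpha;
  const double log1mE0 = std::log(1.0 - E0);
  const double k1 = 7.0 * E0, k2 = 2.0, k3 = 2.0 * E0 - 0.2;

  std::vector<double> x(n, 0.0), s(n, 0.0), f(n, 1.0), v(n, 1.0), q(n, 1.0);
  std::vector<double> M(n * n);
  // RK4 workspaces: 4 slope sets and a midpoint state
  std::vector<double> kx(4 * n), ks(4 * n), kf(4 * n), kv(4 * n), kq(4 * n);
  std::vector<double> tx(n), tss(n), tf(n), tv(n), tq(n);
  std::vector<double> tau_v(tau.begin(), tau.end());

  NumericMatrix bold(n_samples, n);
  bool ok = true;
  double fail_time = NA_REAL;
  int sample_row = 0;
  const double blow_up = 1e4;

  std::vector<double> urow(m);
  for (int step = 0; step < n_steps && ok; ++step) {
    for (int k = 0; k < m; ++k) urow[k] = U(step, k);
    const double* u = urow.data();

    const double half = dt / 2.0;
    const double wt[4] = {0.0, half, half, dt};
    for (int stage = 0; stage < 4; ++stage) {
      const double* px; const double* ps; const double* pf;
      const double* pv; const double* pq;
      if (stage == 0) {
        px = x.data(); ps = s.data(); pf = f.data();
        pv = v.data(); pq = q.data();
      } else {
        const int prev = stage - 1;
        for (int i = 0; i < n; ++i) {
          tx[i] = x[i] + wt[stage] * kx[prev * n + i];
          tss[i] = s[i] + wt[stage] * ks[prev * n + i];
          tf[i] = f[i] + wt[stage] * kf[prev * n + i];
          tv[i] = v[i] + wt[stage] * kv[prev * n + i];
          tq[i] = q[i] + wt[stage] * kq[prev * n + i];
        }
        px = tx.data(); ps = tss.data(); pf = tf.data();
        pv = tv.data(); pq = tq.data();
      }
      if (!deriv(Aflat, n, Bnz, Dnz, Cflat, m, u, px, ps, pf, pv, pq,
                 tau_v.data(), kappa, gamma, inv_alpha, E0, log1mE0,
                 &kx[stage * n], &ks[stage * n], &kf[stage * n],
                 &kv[stage * n], &kq[stage * n], M)) {
        ok = false; fail_time = step * dt; break;
      }
    }
    if (!ok) break;
    for (int i = 0; i < n; ++i) {
      x[i] += dt / 6.0 * (kx[i] + 2.0 * kx[n + i] + 2.0 * kx[2 * n + i] +
                          kx[3 * n + i]);
      s[i] += dt / 6.0 * (ks[i] + 2.0 * ks[n + i] + 2.0 * ks[2 * n + i] +
                          ks[3 * n + i]);
      f[i] += dt / 6.0 * (kf[i] + 2.0 * kf[n + i] + 2.0 * kf[2 * n + i] +
                          kf[3 * n + i]);
      v[i] += dt / 6.0 * (kv[i] + 2.0 * kv[n + i] + 2.0 * kv[2 * n + i] +
                          kv[3 * n + i]);
      q[i] += dt / 6.0 * (kq[i] + 2.0 * kq[n + i] + 2.0 * kq[2 * n + i] +
                          kq[3 * n + i]);
      if (!std::isfinite(x[i]) || std::fabs(x[i]) > blow_up ||
          !(v[i] > 1e-8) || !(q[i] > 1e-8)) {
        ok = false; fail_time = (step + 1) * dt;
      }
    }
    if (ok && (step + 1) % sample_every == 0 && sample_row < n_samples) {
      for (int i = 0; i < n; ++i)
        bold(sample_row, i) =
          V0 * (k1 * (1.0 - q[i]) + k2 * (1.0 - q[i] / v[i]) +
                k3 * (1.0 - v[i]));
      ++sample_row;
    }
  }
  return List::create(_["bold"] = bold, _["ok"] = ok,
                      _["fail_time"] = fail_time);
}
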