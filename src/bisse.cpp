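#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// State-dependent birth-death ODE system, integrated rootward along a
// branch: y = (E0, E1, D0, D1).
//   E_s' = mu_s - (lambda_s + mu_s + q_s)E_s + q_s E_other + lambda_s E_s^2
//   D_s' = -(lambda_s + mu_s + q_s)D_s + q_s D_other + 2 lambda_s E_s D_s
static inline void bisse_rhs(const double *y, double *dy,
                             double l0, double l1, double m0, double m1,
                             double q01, double q10) {
  const double E0 = y[0], E1 = y[1], D0 = y[2], D1 = y[3];
  const double s0 = l0 + m0 + q01, s1 = l1 + m1 + q10;
  dy[0] = m0 - s0 * E0 + q01 * E1 + l0 * E0 * E0;
  dy[1] = m1 - s1 * E1 + q10 * E0 + l1 * E1 * E1;
  dy[2] = -s0 * D0 + q01 * D1 + 2.0 * l0 * E0 * D0;
  dy[3] = -s1 * D1 + q10 * D0 + 2.0 * l1 * E1 * D1;
}

// Runge-Kutta-Fehlberg 4(5) with adaptive step size. Step-size changes
// are clamped to [h0 * clamp_min, h0 * clamp_max] around the initial
// step h0; the last step is shortened to land exactly on the branch end.
// Returns false on failure (error above tolerance at the minimum step,
// or non-finite state).
static bool rkf45_branch(double *y, double len,
                         double l0, double l1, double m0, double m1,
                         double q01, double q10,
                         double h0, double rel_tol, double abs_tol,
                         double clamp_min, double clamp_max,
                         long *steps, long *rejects) {
  if (len <= 0.0) return true;
  const double hmin = h0 * clamp_min, hmax = h0 * clamp_max;
  double t = 0.0, h = h0;
  if (h > len) h = len;
  double k1[4], k2[4], k3[4], k4[4], k5[4], k6[4], yt[4], y4, y5[4];

  while (t < len) {
    bool shortened = false;
    if (h > len - t) { h = len - t; shortened = true; }
    bisse_rhs(y, k1, l0, l1, m0, m1, q01, q10);
    for (int i = 0; i < 4; ++i) yt[i] = y[i] + h * (0.25 * k1[i]);
    bisse_rhs(yt, k2, l0, l1, m0, m1, q01, q10);
    for (int i = 0; i < 4; ++i)
      yt[i] = y[i] + h * (3.0 / 32.0 * k1[i] + 9.0 / 32.0 * k2[i]);
    bisse_rhs(yt, k3, l0, l1, m0, m1, q01, q10);
    for (int i = 0; i < 4; ++i)
      yt[i] = y[i] + h * (1932.0 / 2197.0 * k1[i] - 7200.0 / 2197.0 * k2[i] +
                          7296.0 / 2197.0 * k3[i]);
    bisse_rhs(yt, k4, l0, l1, m0, m1, q01, q10);
    for (int i = 0; i < 4; ++i)
      yt[i] = y[i] + h * (439.0 / 216.0 * k1[i] - 8.0 * k2[i] +
                          3680.0 / 513.0 * k3[i] - 845.0 / 4104.0 * k4[i]);
    bisse_rhs(yt, k5, l0, l1, m0, m1, q01, q10);
    for (int i = 0; i < 4; ++i)
      yt[i] = y[i] + h * (-8.0 / 27.0 * k1[i] + 2.0 * k2[i] -
                          3544.0 / 2565.0 * k3[i] + 1859.0 / 4104.0 * k4[i] -
                          11.0 / 40.0 * k5[i]);
    bisse_rhs(yt, k6, l0, l1, m0, m1, q01, q10);

    double errmax = 0.0;
    for (int i = 0; i < 4; ++i) {
      y4 = y[i] + h * (25.0 / 216.0 * k1[i] + 1408.0 / 2565.0 * k3[i] +
                       2197.0 / 4104.0 * k4[i] - 0.2 * k5[i]);
      y5[i] = y[i] + h * (16.0 / 135.0 * k1[i] + 6656.0 / 12825.0 * k3[i] +
                          28561.0 / 56430.0 * k4[i] - 9.0 / 50.0 * k5[i] +
                          2.0 / 55.0 * k6[i]);
      const double sc = abs_tol + rel_tol * std::max(std::fabs(y[i]),
                                                     std::fabs(y5[i]));
      const double e = std::fabs(y5[i] - y4) / sc;
      if (e > errmax) errmax = e;
      if (!std::isfinite(y5[i])) errmax = HUGE_VAL;
    }

    if (errmax <= 1.0) { // accept (local extrapolation with the 5th-order value)
      t += h;
      for (int i = 0; i < 4; ++i) y[i] = y5[i];
      // keep extinction probabilities inside [0,1] against roundoff
      for (int i = 0; i < 2; ++i) {
        if (y[i] < 0.0) y[i] = 0.0;
        if (y[i] > 1.0) y[i] = 1.0;
      }
      ++*steps;
    } else {
      ++*rejects;
      // the clamp forbids shrinking further: error above tolerance at the
      // minimum step is an integration failure
      if (h <= hmin * (1.0 + 1e-12)) return false;
      (void)shortened;
    }
    double fac = (errmax > 0.0) ? 0.9 * std::pow(errmax, -0.2) : 5.0;
    if (fac < 0.2) fac = 0.2;
    if (fac > 5.0) fac = 5.0;
    h *= fac;
    if (h < hmin) h = hmin;
    if (h > hmax) h = hmax;
  }
  return true;
}

// Post-order pruning of the BiSSE likelihood over a tree given in ape
// edge-matrix form (edges already sorted in postorder: every child edge
// appears before its parent's edge). Node indexing follows ape: tips are
// 1..n_tip, the root is n_tip + 1.
// [[Rcpp::export(name = ".bisse_loglik_cpp")]]
List bisse_loglik_cpp(IntegerVector edge_parent, IntegerVector edge_child,
                      NumericVector edge_length, int n_tip,
                      IntegerVector tip_state, NumericVector rates,
                      NumericVector root_weights,
                      double initial_step, double rel_tol, double abs_tol,
                      double clamp_min, double clamp_max) {
  const int n_edge = edge_parent.size();
  const int n_all = n_tip + n_tip; // n_tip - 1 internal nodes + root slot fits
  const double l0 = rates[0], l1 = rates[1], m0 = rates[2], m1 = rates[3],
               q01 = rates[4], q10 = rates[5];

  // per-node combined state at the node itself (before its own branch)
  std::vector<double> E0(n_all, 0.0), E1(n_all, 0.0),
      D0(n_all, 0.0), D1(n_all, 0.0);
  std::vector<int> seen(n_all, 0);
  double logscale = 0.0;
  long steps = 0, rejects = 0;
  bool ok = true;
  int bad_node = -1;
  double emismatch = 0.0;

  for (int e = 0; e < n_edge && ok; ++e) {
    const int child = edge_child[e] - 1; // 0-based
    const int par = edge_parent[e] - 1;
    double y[4];
    if (edge_child[e] <= n_tip) {
      const int st = tip_state[edge_child[e] - 1];
      y[0] = 0.0; y[1] = 0.0;
      y[2] = (st == 0) ? 1.0 : 0.0;
      y[3] = (st == 1) ? 1.0 : 0.0;
    } else {
      if (seen[child] != 2) { ok = false; bad_node = edge_child[e]; break; }
      y[0] = E0[child]; y[1] = E1[child];
      y[2] = D0[child]; y[3] = D1[child];
    }
    if (!rkf45_branch(y, edge_length[e], l0, l1, m0, m1, q01, q10,
                      initial_step, rel_tol, abs_tol, clamp_min, clamp_max,
                      &steps, &rejects)) {
      ok = false; bad_node = edge_child[e]; break;
    }
    // merge into the parent slot
    if (seen[par] == 0) {
      E0[par] = y[0]; E1[par] = y[1]; D0[par] = y[2]; D1[par] = y[3];
      seen[par] = 1;
    } else {
      const double dE = std::max(std::fabs(E0[par] - y[0]),
                                 std::fabs(E1[par] - y[1]));
      if (dE > emismatch) emismatch = dE;
      E0[par] = 0.5 * (E0[par] + y[0]);
      E1[par] = 0.5 * (E1[par] + y[1]);
      D0[par] = l0 * D0[par] * y[2];
      D1[par] = l1 * D1[par] * y[3];
      const double s = D0[par] + D1[par];
      if (s > 0.0 && std::isfinite(s)) {
        D0[par] /= s; D1[par] /= s;
        logscale += std::log(s);
      } else if (!std::isfinite(s)) {
        ok = false; bad_node = edge_parent[e];
      }
      seen[par] = 2;
    }
  }

  double ll = R_NegInf;
  const int root = n_tip; // 0-based index of node n_tip + 1
  if (ok && seen[root] == 2) {
    const double L = root_weights[0] * D0[root] + root_weights[1] * D1[root];
    ll = (L > 0.0) ? std::log(L) + logscale : R_NegInf;
    if (!std::isfinite(ll) && L > 0.0) ok = false;
  } else if (ok) {
    ok = false; bad_node = root + 1;
  }

  return List::create(_["loglik"] = ll, _["ok"] = ok,
                      _["steps"] = (double)steps,
                      _["rejects"] = (double)rejects,
                      _["e_mismatch"] = emismatch,
                      _["bad_node"] = bad_node,
                      _["root_E"] = NumericVector::create(E0[root], E1[root]),
                      _["root_D"] = NumericVector::create(D0[root], D1[root]),
                      _["logscale"] = logscale);
}

// Single-branch integration, exposed for closed-form validation of the
// ODE system. init = (E0, E1, D0, D1); rates unvalidated on purpose so
// degenerate cases (all-zero speciation) can be exercised.
// [[Rcpp::export(name = ".bisse_branch_cpp")]]
List bisse_branch_cpp(NumericVector init, NumericVector rates, double len,
                      double initial_step, double rel_tol, double abs_tol,
                      double clamp_min, double clamp_max) {
  double y[4] = {init[0], init[1], init[2], init[3]};
  long steps = 0, rejects = 0;
  bool ok = rkf45_branch(y, len, rates[0], rates[1], rates[2], rates[3],
                         rates[4], rates[5], initial_step, rel_tol, abs_tol,
                         clamp_min, clamp_max, &steps, &rejects);
  return List::create(_["state"] = NumericVector::create(y[0], y[1], y[2], y[3]),
                      _["ok"] = ok, _["steps"] = (double)steps,
                      _["rejects"] = (double)rejects);
}
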