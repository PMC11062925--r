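// Backward-Euler integrator for lumped-parameter hemodynamic networks.
//
// Unknown layout: y = [node pressures (n_nodes), element flows (n_flows),
// chamber volumes (n_chambers)]. The DAE is E*ydot + g(y, t) = 0 with a
// constant (singular) mass matrix E holding capacitor, inductor and
// chamber-volume terms, and g holding Kirchhoff node balances, element
// constitutive laws and chamber elastance relations. Valves are smooth
// diodes so the residual stays C1 and plain Newton converges.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct NetSpec {
  int n_nodes, n_flows, n_chambers, n;
  arma::imat elem_i;   // m x 4: type, node_a, node_b, flow_idx (0-based, -1 = ground)
  arma::mat  elem_p;   // m x 5: R, L, p1, p2, p3
  arma::imat cap_i;    // k x 2: node, ref_node (-1 none)
  arma::mat  cap_p;    // k x 2: C, ref_scale
  arma::ivec ch_node;  // c
  arma::mat  ch_p;     // c x 5: Emax, Emin, V0, t_on, duration
  double period;
};

NetSpec parse_spec(const List& spec) {
  NetSpec s;
  s.n_nodes = as<int>(spec["n_nodes"]);
  s.n_flows = as<int>(spec["n_flows"]);
  s.n_chambers = as<int>(spec["n_chambers"]);
  s.n = s.n_nodes + s.n_flows + s.n_chambers;
  s.elem_i = as<arma::imat>(spec["elem_i"]);
  s.elem_p = as<arma::mat>(spec["elem_p"]);
  s.cap_i = as<arma::imat>(spec["cap_i"]);
  s.cap_p = as<arma::mat>(spec["cap_p"]);
  s.ch_node = as<arma::ivec>(spec["ch_node"]);
  s.ch_p = as<arma::mat>(spec["ch_p"]);
  s.period = as<double>(spec["period"]);
  return s;
}

arma::mat mass_matrix(const NetSpec& s) {
  arma::mat E(s.n, s.n, arma::fill::zeros);
  for (arma::uword j = 0; j < s.cap_i.n_rows; ++j) {
    int nd = s.cap_i(j, 0), rf = s.cap_i(j, 1);
    double C = s.cap_p(j, 0), sc = s.cap_p(j, 1);
    E(nd, nd) -= C;
    if (rf >= 0) E(nd, rf) += C * sc;
  }
  for (int c = 0; c < s.n_chambers; ++c) {
    E(s.ch_node(c), s.n_nodes + s.n_flows + c) -= 1.0;
  }
  for (arma::uword m = 0; m < s.elem_i.n_rows; ++m) {
    if (s.elem_i(m, 0) == 1) {  // RL
      int f = s.elem_i(m, 3);
      E(s.n_nodes + f, s.n_nodes + f) -= s.elem_p(m, 1);
    }
  }
  return E;
}

double activation(double t, double t_on, double dur, double T) {
  // (t - t_on) mod T without std::fmod (keeps the binary portable across
  // the glibc symbol-version bump of fmod)
  double x = t - t_on;
  double ph = x - std::floor(x / T) * T;
  if (ph < 0) ph += T;
  if (ph >= dur) return 0.0;
  return 0.5 * (1.0 - std::cos(2.0 * M_PI * ph / dur));
}

// algebraic residual g(y, t) and its Jacobian
void algebraic(const NetSpec& s, const arma::vec& y, double t,
               arma::vec& g, arma::mat& J, bool want_jac) {
  g.zeros(s.n);
  if (want_jac) J.zeros(s.n, s.n);
  const int nN = s.n_nodes, nF = s.n_flows;

  auto P = [&](int nd) { return nd < 0 ? 0.0 : y(nd); };

  for (arma::uword m = 0; m < s.elem_i.n_rows; ++m) {
    int type = s.elem_i(m, 0), a = s.elem_i(m, 1), b = s.elem_i(m, 2);
    int f = s.elem_i(m, 3);
    int row = nN + f;
    double q = y(nN + f);
    double R = s.elem_p(m, 0);
    double p1 = s.elem_p(m, 2), p2 = s.elem_p(m, 3), p3 = s.elem_p(m, 4);
    // node balances: flow runs a -> b
    if (a >= 0) { g(a) -= q; if (want_jac) J(a, nN + f) -= 1.0; }
    if (b >= 0) { g(b) += q; if (want_jac) J(b, nN + f) += 1.0; }
    double dP = P(a) - P(b);
    switch (type) {
    case 0:   // resistor
    case 1: { // resistor + inductor (L lives in the mass matrix)
      g(row) = dP - R * q;
      if (want_jac) {
        if (a >= 0) J(row, a) += 1.0;
        if (b >= 0) J(row, b) -= 1.0;
        J(row, nN + f) -= R;
      }
      break;
    }
    case 2: { // smooth diode valve: p1 = R_leak, p2 = width
      double w = p2;
      double sg = 1.0 / (1.0 + std::exp(-dP / w));
      double G = sg / R + (1.0 - sg) / p1;
      double dG = sg * (1.0 - sg) / w * (1.0 / R - 1.0 / p1);
      g(row) = q - dP * G;
      if (want_jac) {
        double dd = -(G + dP * dG);
        if (a >= 0) J(row, a) += dd;
        if (b >= 0) J(row, b) -= dd;
        J(row, nN + f) += 1.0;
      }
      break;
    }
    case 3: { // pressure source: p1 = set pressure
      g(row) = dP - p1;
      if (want_jac) {
        if (a >= 0) J(row, a) += 1.0;
        if (b >= 0) J(row, b) -= 1.0;
      }
      break;
    }
    case 4: { // flow source: q = p1 + p2 sin(p3 t)
      g(row) = q - (p1 + p2 * std::sin(p3 * t));
      if (want_jac) J(row, nN + f) += 1.0;
      break;
    }
    case 5: { // stenosis: linear + quadratic loss, p1 = K
      g(row) = dP - R * q - p1 * q * std::fabs(q);
      if (want_jac) {
        if (a >= 0) J(row, a) += 1.0;
        if (b >= 0) J(row, b) -= 1.0;
        J(row, nN + f) -= R + 2.0 * p1 * std::fabs(q);
      }
      break;
    }
    default:
      stop("unknown element type");
    }
  }

  for (int c = 0; c < s.n_chambers; ++c) {
    int nd = s.ch_node(c);
    int row = nN + nF + c;
    double Emax = s.ch_p(c, 0), Emin = s.ch_p(c, 1), V0 = s.ch_p(c, 2);
    double a_t = activation(t, s.ch_p(c, 3), s.ch_p(c, 4), s.period);
    double El = Emin + (Emax - Emin) * a_t;
    double V = y(row);
    g(row) = y(nd) - El * (V - V0);
    if (want_jac) {
      J(row, nd) += 1.0;
      J(row, row) -= El;
    }
  }
}

// sparse triplet form of the (very sparse) mass matrix
struct MassTriplets {
  std::vector<int> i, j;
  std::vector<double> v;
  void from_dense(const arma::mat& E) {
    for (arma::uword c = 0; c < E.n_cols; ++c)
      for (arma::uword r = 0; r < E.n_rows; ++r)
        if (E(r, c) != 0.0) { i.push_back(r); j.push_back(c);
                              v.push_back(E(r, c)); }
  }
};

// workspace reused across steps to avoid per-step allocation
struct Work {
  long n_iter = 0, n_lu = 0;
  arma::vec g, r, dy;
  arma::mat Ja, Jbe, L, U;
  arma::uvec perm;
  explicit Work(int n)
      : g(n), r(n), dy(n), Ja(n, n), Jbe(n, n), L(n, n), U(n, n), perm(n) {}
};

// in-place solve of (L U) x = r(perm) with L, U from arma::lu
void lu_solve(const Work& w, const arma::vec& r, arma::vec& x) {
  const int n = r.n_elem;
  for (int i = 0; i < n; ++i) {
    double s = r(w.perm(i));
    for (int j = 0; j < i; ++j) s -= w.L(i, j) * x(j);
    x(i) = s / w.L(i, i);
  }
  for (int i = n - 1; i >= 0; --i) {
    double s = x(i);
    for (int j = i + 1; j < n; ++j) s -= w.U(i, j) * x(j);
    x(i) = s / w.U(i, i);
  }
}

// one backward-Euler step; modified Newton that reuses one LU
// factorization per step (the Jacobian changes only through the smooth
// valves and the chamber elastance), refactoring if convergence stalls
bool be_step(const NetSpec& s, const MassTriplets& Et, double dt,
             const arma::vec& y_prev, double t_new, arma::vec& y, Work& w) {
  bool have_lu = false;
  double last_rel = arma::datum::inf;
  for (int it = 0; it < 20; ++it) {
    w.n_iter++;
    bool refactor = !have_lu || (it >= 4 && last_rel > 1e-6);
    algebraic(s, y, t_new, w.g, w.Ja, refactor);
    w.r = w.g;
    for (size_t k = 0; k < Et.v.size(); ++k) {
      w.r(Et.i[k]) += Et.v[k] * (y(Et.j[k]) - y_prev(Et.j[k])) / dt;
    }
    if (refactor) {
      w.Jbe = w.Ja;
      for (size_t k = 0; k < Et.v.size(); ++k) {
        w.Jbe(Et.i[k], Et.j[k]) += Et.v[k] / dt;
      }
      arma::mat P;
      w.n_lu++;
      if (!arma::lu(w.L, w.U, P, w.Jbe)) return false;
      // P * X reorders rows: row i of P has a 1 in column perm(i)
      for (arma::uword i = 0; i < P.n_rows; ++i) {
        w.perm(i) = arma::index_max(P.row(i));
      }
      have_lu = true;
    }
    lu_solve(w, w.r, w.dy);
    if (!w.dy.is_finite()) return false;
    y -= w.dy;
    last_rel = arma::norm(w.dy) / (arma::norm(y) + 1.0);
    if (last_rel < 1e-11) return true;
  }
  return last_rel < 1e-7;
}

// step with recursive halving on Newton failure
bool be_step_adaptive(const NetSpec& s, const MassTriplets& Et,
                      const arma::vec& y_prev, double t_prev, double dt,
                      arma::vec& y, int depth, Work& w) {
  arma::vec ynew = y_prev;
  if (be_step(s, Et, dt, y_prev, t_prev + dt, ynew, w)) {
    y = ynew;
    return true;
  }
  if (depth >= 8) return false;
  arma::vec ymid = y_prev;
  if (!be_step_adaptive(s, Et, y_prev, t_prev, dt / 2, ymid, depth + 1, w))
    return false;
  return be_step_adaptive(s, Et, ymid, t_prev + dt / 2, dt / 2, y,
                          depth + 1, w);
}

}  // namespace

// [[Rcpp::export(name = ".lpn_run_cpp")]]
List lpn_run_cpp(List spec, arma::vec y0, double dt, int steps_per_cycle,
                 int max_cycles, double tol) {
  NetSpec s = parse_spec(spec);
  if ((int)y0.n_elem != s.n) stop("state vector length mismatch");
  arma::mat E = mass_matrix(s);
  MassTriplets Et;
  Et.from_dense(E);

  arma::mat traj(steps_per_cycle + 1, s.n);
  arma::vec y = y0, y_cycle_prev = y0;
  arma::vec conv_hist(max_cycles, arma::fill::value(NA_REAL));
  int cycles = 0;
  bool converged = false;
  double t0 = 0.0;
  Work w(s.n);

  for (int cyc = 0; cyc < max_cycles; ++cyc) {
    traj.row(0) = y.t();
    for (int k = 0; k < steps_per_cycle; ++k) {
      double t_prev = t0 + k * dt;
      arma::vec ynew = y;
      if (!be_step(s, Et, dt, y, t_prev + dt, ynew, w)) {
        ynew = y;
        if (!be_step_adaptive(s, Et, y, t_prev, dt, ynew, 0, w)) {
          stop("Newton failed to converge at t = %g even after step halving",
               t_prev);
        }
      }
      y = ynew;
      traj.row(k + 1) = y.t();
    }
    t0 += steps_per_cycle * dt;
    cycles = cyc + 1;
    // blockwise relative cycle-to-cycle change
    double m = 0.0;
    int ofs[4] = {0, s.n_nodes, s.n_nodes + s.n_flows, s.n};
    for (int b = 0; b < 3; ++b) {
      if (ofs[b + 1] == ofs[b]) continue;
      arma::vec cur = y.subvec(ofs[b], ofs[b + 1] - 1);
      arma::vec prev = y_cycle_prev.subvec(ofs[b], ofs[b + 1] - 1);
      double scale = arma::abs(cur).max() + 1e-12;
      double d = arma::abs(cur - prev).max() / scale;
      if (d > m) m = d;
    }
    conv_hist(cyc) = m;
    y_cycle_prev = y;
    if (cyc > 0 && m < tol) { converged = true; break; }
  }

  return List::create(
    _["traj"] = traj, _["y_end"] = y, _["cycles"] = cycles,
    _["converged"] = converged, _["conv_history"] = conv_hist,
    _["dt"] = dt, _["steps_per_cycle"] = steps_per_cycle,
    _["n_iter"] = (double)w.n_iter, _["n_lu"] = (double)w.n_lu);
}
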