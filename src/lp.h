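#ifndef SYNCOL_LP_H
#define SYNCOL_LP_H

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace syncol_lp {

const double PIV_TOL = 1e-9;   // reduced-cost / pivot tolerance
const double FEAS_TOL = 1e-7;  // phase-1 residual tolerance
const double BIG = 1e30;

struct BoundedLP {
  int m, nstruct, ntot;          // rows, structural vars, total vars
  std::vector<double> T;         // tableau, m x ntot, row-major (= Binv * A)
  std::vector<double> xB;        // values of basic variables
  std::vector<int> basis;        // basic variable of each row
  std::vector<int> vstat;        // 0 = nonbasic at lower, 1 = at upper, 2 = basic
  std::vector<double> lo, up;

  double &t(int i, int j) { return T[(size_t)i * ntot + j]; }

  // value of variable j in the current basic solution
  double value(int j) const {
    if (vstat[j] == 2) {
      for (int i = 0; i < m; ++i) if (basis[i] == j) return xB[i];
      return 0.0;
    }
    return vstat[j] == 0 ? lo[j] : up[j];
  }

  double objective(const std::vector<double> &cc) const {
    double z = 0.0;
    for (int j = 0; j < ntot; ++j) {
      if (vstat[j] == 2) continue;
      if (cc[j] != 0.0) z += cc[j] * (vstat[j] == 0 ? lo[j] : up[j]);
    }
    for (int i = 0; i < m; ++i) z += cc[basis[i]] * xB[i];
    return z;
  }

  // one simplex phase on objective cc; returns 0 on optimal, 2 on iteration cap
  int optimise(const std::vector<double> &cc, int maxit) {
    std::vector<double> yrow(m), dred(ntot);
    int dantzig_limit = maxit / 2;
    for (int iter = 0; iter < maxit; ++iter) {
      bool bland = iter > dantzig_limit;
      for (int i = 0; i < m; ++i) yrow[i] = cc[basis[i]];
      // reduced costs d_j = c_j - y' T_j for nonbasic j
      int enter = -1;
      double best = PIV_TOL;
      for (int j = 0; j < ntot; ++j) {
        if (vstat[j] == 2) continue;
        double d = cc[j];
        for (int i = 0; i < m; ++i) {
          double yv = yrow[i];
          if (yv != 0.0) d -= yv * t(i, j);
        }
        dred[j] = d;
        double viol = 0.0;
        if (vstat[j] == 0 && d < -PIV_TOL) viol = -d;       // raise from lower
        else if (vstat[j] == 1 && d > PIV_TOL) viol = d;    // lower from upper
        if (viol > 0.0) {
          if (bland) { enter = j; break; }
          if (viol > best) { best = viol; enter = j; }
        }
      }
      if (enter < 0) return 0;  // optimal
      double dir = vstat[enter] == 0 ? 1.0 : -1.0;
      // ratio test
      double tmax = up[enter] - lo[enter];
      int leave = -1, leave_to = 0;
      for (int i = 0; i < m; ++i) {
        double alpha = dir * t(i, enter);
        double tk; int to;
        if (alpha > PIV_TOL) {          // basic variable decreases
          tk = (xB[i] - lo[basis[i]]) / alpha; to = 0;
        } else if (alpha < -PIV_TOL) {  // basic variable increases
          tk = (xB[i] - up[basis[i]]) / alpha; to = 1;
        } else continue;
        if (tk < 0.0) tk = 0.0;
        bool better = tk < tmax - 1e-12;
        bool tie = std::fabs(tk - tmax) <= 1e-12 && leave >= 0 &&
                   basis[i] < basis[leave];
        if (better || tie) { tmax = tk; leave = i; leave_to = to; }
      }
      if (tmax >= BIG) return 3;  // unbounded (cannot occur with finite bounds)
      double step = tmax;
      for (int i = 0; i < m; ++i) xB[i] -= step * dir * t(i, enter);
      if (leave < 0) {            // bound-to-bound flip, no basis change
        vstat[enter] = 1 - vstat[enter];
        continue;
      }
      double enter_val = (dir > 0 ? lo[enter] : up[enter]) + dir * step;
      // pivot on (leave, enter)
      double piv = t(leave, enter);
      double inv = 1.0 / piv;
      for (int j = 0; j < ntot; ++j) t(leave, j) *= inv;
      for (int i = 0; i < m; ++i) {
        if (i == leave) continue;
        double f = t(i, enter);
        if (f != 0.0) {
          for (int j = 0; j < ntot; ++j) t(i, j) -= f * t(leave, j);
        }
      }
      vstat[basis[leave]] = leave_to;
      basis[leave] = enter;
      vstat[enter] = 2;
      xB[leave] = enter_val;
    }
    return 2;
  }
};

// Build the tableau with artificial variables and run phase 1 for A x = 0.
// Returns 0 feasible, 1 infeasible, 2 iteration cap.
inline int phase1(BoundedLP &lp, const NumericMatrix &A,
           const std::vector<double> &lo, const std::vector<double> &up,
           int maxit) {
  int m = A.nrow(), n = A.ncol();
  lp.m = m; lp.nstruct = n; lp.ntot = n + m;
  lp.T.assign((size_t)m * lp.ntot, 0.0);
  lp.lo = lo; lp.up = up;
  lp.lo.resize(lp.ntot); lp.up.resize(lp.ntot);
  lp.basis.resize(m); lp.vstat.assign(lp.ntot, 0);
  lp.xB.resize(m);
  // residual of starting point (all structural at lower bound), rhs b = 0
  std::vector<double> r(m, 0.0);
  for (int j = 0; j < n; ++j) {
    double lj = lo[j];
    if (lj != 0.0) for (int i = 0; i < m; ++i) r[i] -= A(i, j) * lj;
  }
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) lp.t(i, j) = A(i, j);
  for (int i = 0; i < m; ++i) {
    int aj = n + i;
    double sgn = r[i] >= 0.0 ? 1.0 : -1.0;
    lp.t(i, aj) = sgn;
    lp.lo[aj] = 0.0; lp.up[aj] = BIG;
    lp.basis[i] = aj; lp.vstat[aj] = 2;
    lp.xB[i] = std::fabs(r[i]);
    if (sgn < 0.0) {  // normalise row so the artificial has coefficient +1
      for (int j = 0; j < n; ++j) lp.t(i, j) = -lp.t(i, j);
      lp.t(i, aj) = 1.0;
    }
  }
  std::vector<double> cc(lp.ntot, 0.0);
  for (int i = 0; i < m; ++i) cc[n + i] = 1.0;
  int st = lp.optimise(cc, maxit);
  if (st != 0) return 2;
  double z1 = lp.objective(cc);
  if (z1 > FEAS_TOL) return 1;
  // freeze artificials at zero for all later phases
  for (int i = 0; i < m; ++i) { lp.up[n + i] = 0.0; }
  return 0;
}

// Warm-started lexicographic stages: reuse the factorised tableau from the
// previous node (only bounds differ between nodes), recompute the basic
// solution under the new bounds, and fall back to a cold phase-1 start if
// the old basis is no longer primal feasible.
inline int lex_warm(BoundedLP &lp, bool &have_basis, const NumericMatrix &A,
                    std::vector<double> &lo, std::vector<double> &up,
                    const IntegerVector &obj_idx, const IntegerVector &sense,
                    double fix_rtol, double fix_atol, int maxit,
                    std::vector<double> &xout) {
  int n = A.ncol();
  bool warm_ok = false;
  if (have_basis) {
    // install new bounds (artificials keep theirs: fixed at zero)
    for (int j = 0; j < n; ++j) { lp.lo[j] = lo[j]; lp.up[j] = up[j]; }
    // xB = -sum_{nonbasic j} T_j x_j  (rhs b = 0)
    std::fill(lp.xB.begin(), lp.xB.end(), 0.0);
    for (int j = 0; j < lp.ntot; ++j) {
      if (lp.vstat[j] == 2) continue;
      double xj = lp.vstat[j] == 0 ? lp.lo[j] : lp.up[j];
      if (xj != 0.0)
        for (int i = 0; i < lp.m; ++i) lp.xB[i] -= lp.t(i, j) * xj;
    }
    warm_ok = true;
    for (int i = 0; i < lp.m; ++i) {
      int b = lp.basis[i];
      if (lp.xB[i] < lp.lo[b] - 1e-8 || lp.xB[i] > lp.up[b] + 1e-8) {
        warm_ok = false; break;
      }
    }
  }
  if (!warm_ok) {
    int st = phase1(lp, A, lo, up, maxit);
    have_basis = st == 0;
    if (st != 0) return st;
  }
  std::vector<double> cc(lp.ntot, 0.0);
  for (int k = 0; k < obj_idx.size(); ++k) {
    int j = obj_idx[k] - 1;
    std::fill(cc.begin(), cc.end(), 0.0);
    cc[j] = sense[k] > 0 ? -1.0 : 1.0;
    int st = lp.optimise(cc, maxit);
    if (st != 0) { have_basis = false; return st; }
    double z = lp.value(j);
    double tol = std::max(std::fabs(z) * fix_rtol, fix_atol);
    lp.lo[j] = std::max(lp.lo[j], z - tol);
    lp.up[j] = std::min(lp.up[j], z + tol);
  }
  xout.assign(n, 0.0);
  for (int j = 0; j < n; ++j) xout[j] = lp.value(j);
  return 0;
}



// Lexicographic solve with a starvation fallback.  When the
// maintenance-constrained problem is infeasible (gas uptake too small to
// cover the mandatory ATP drain), the cell is modelled as starving: the
// maintenance lower bound is relaxed and the achievable maintenance flux
// (capped at the demand) is maximised as a prepended objective, after
// which the usual objective sequence runs (growth is then zero because
// every available ATP went to maintenance).  This keeps the flux response
// continuous across the growth/no-growth boundary, which a hard
// "all fluxes zero" contract would turn into a sliding-mode discontinuity
// for the outer ODE integrator.
// Returns 0 = optimal, 2 = starving (solved with relaxed maintenance),
// >2 solver failure.
inline int lex_with_starvation(BoundedLP &lp, bool &have_basis,
                               const NumericMatrix &A,
                               std::vector<double> &lo, std::vector<double> &up,
                               const IntegerVector &obj_idx,
                               const IntegerVector &sense,
                               int atpm_idx, double atpm_demand,
                               double fix_rtol, double fix_atol, int maxit,
                               std::vector<double> &xout) {
  std::vector<double> lo1(lo), up1(up);
  int st = lex_warm(lp, have_basis, A, lo1, up1, obj_idx, sense,
                    fix_rtol, fix_atol, maxit, xout);
  if (st != 1 || atpm_idx < 0) return st;
  // starvation problem: maintenance in [0, demand], maximised first
  std::vector<double> lo2(lo), up2(up);
  lo2[atpm_idx] = 0.0;
  if (up2[atpm_idx] > atpm_demand) up2[atpm_idx] = atpm_demand;
  IntegerVector obj2(obj_idx.size() + 1), sen2(sense.size() + 1);
  obj2[0] = atpm_idx + 1; sen2[0] = 1;
  for (int k = 0; k < obj_idx.size(); ++k) {
    obj2[k + 1] = obj_idx[k]; sen2[k + 1] = sense[k];
  }
  bool hb2 = false;
  st = lex_warm(lp, hb2, A, lo2, up2, obj2, sen2, fix_rtol, fix_atol,
                maxit, xout);
  have_basis = false;  // basis belongs to the modified problem
  if (st != 0) return st == 1 ? 1 : st;
  return 2;
}

}  // namespace syncol_lp

#endif
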