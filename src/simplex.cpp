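// Dense bounded-variable primal simplex and the lexicographic flux-balance
// driver used at every axial node of the column model.
//
// Problem form: min c'x  s.t.  A x = b,  l <= x <= u  with all bounds finite
// (flux bounds in constraint-based models are finite by construction).
// Two phases: artificial variables close the residual of the starting point
// (all structural variables at their lower bounds), then the true objective
// is optimised.  Pivoting is Dantzig's rule with lowest-index tie-breaking,
// falling back to Bland's rule after a fixed iteration count so the solver
// is both fast in practice and guaranteed to terminate.  All choices are
// deterministic, so repeated solves are bitwise identical.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

#include "lp.h"
using namespace syncol_lp;


//' @noRd
// [[Rcpp::export(name = ".lp_solve_cpp")]]
List lp_solve_cpp(NumericMatrix A, NumericVector lower, NumericVector upper,
                  NumericVector objective, bool maximize, int maxit = 20000) {
  int m = A.nrow(), n = A.ncol();
  std::vector<double> lo(lower.begin(), lower.end());
  std::vector<double> up(upper.begin(), upper.end());
  BoundedLP lp;
  int st = phase1(lp, A, lo, up, maxit);
  if (st != 0) {
    return List::create(_["status"] = st, _["x"] = R_NilValue,
                        _["objval"] = NA_REAL);
  }
  std::vector<double> cc(lp.ntot, 0.0);
  for (int j = 0; j < n; ++j) cc[j] = maximize ? -objective[j] : objective[j];
  st = lp.optimise(cc, maxit);
  NumericVector x(n);
  for (int j = 0; j < n; ++j) x[j] = lp.value(j);
  double z = lp.objective(cc);
  return List::create(_["status"] = st, _["x"] = x,
                      _["objval"] = maximize ? -z : z);
}

// Solve the ordered objective sequence, fixing each optimum via two-sided
// bounds before the next stage.  Objectives are single flux coordinates
// (signs handled by `sense`: +1 maximise, -1 minimise), so fixing an optimum
// tightens one variable's bounds.  The phase-1 basis is reused across stages.
static int lex_core(BoundedLP &lp, const NumericMatrix &A,
                    std::vector<double> &lo, std::vector<double> &up,
                    const IntegerVector &obj_idx, const IntegerVector &sense,
                    double fix_rtol, double fix_atol, int maxit,
                    std::vector<double> &xout) {
  int n = A.ncol();
  int st = phase1(lp, A, lo, up, maxit);
  if (st != 0) return st;
  std::vector<double> cc(lp.ntot, 0.0);
  for (int k = 0; k < obj_idx.size(); ++k) {
    int j = obj_idx[k] - 1;
    double sgn = sense[k] > 0 ? -1.0 : 1.0;  // minimise internally
    std::fill(cc.begin(), cc.end(), 0.0);
    cc[j] = sgn;
    st = lp.optimise(cc, maxit);
    if (st != 0) return st;
    double z = lp.value(j);
    double tol = std::max(std::fabs(z) * fix_rtol, fix_atol);
    lp.lo[j] = std::max(lp.lo[j], z - tol);
    lp.up[j] = std::min(lp.up[j], z + tol);
  }
  xout.assign(n, 0.0);
  for (int j = 0; j < n; ++j) xout[j] = lp.value(j);
  return 0;
}

//' @noRd
// [[Rcpp::export(name = ".lex_fba_cpp")]]
List lex_fba_cpp(NumericMatrix A, NumericVector lower, NumericVector upper,
                 IntegerVector obj_idx, IntegerVector sense,
                 int atpm_idx = -1, double atpm_demand = 0,
                 double fix_rtol = 1e-9, double fix_atol = 1e-12,
                 int maxit = 20000) {
  std::vector<double> lo(lower.begin(), lower.end());
  std::vector<double> up(upper.begin(), upper.end());
  BoundedLP lp;
  bool have = false;
  std::vector<double> x;
  int st = lex_with_starvation(lp, have, A, lo, up, obj_idx, sense,
                               atpm_idx - 1, atpm_demand,
                               fix_rtol, fix_atol, maxit, x);
  if (st != 0 && st != 2)
    return List::create(_["status"] = st, _["x"] = R_NilValue);
  return List::create(_["status"] = st,
                      _["x"] = NumericVector(x.begin(), x.end()));
}

// One lexicographic solve per row of `uptake`: column k of `uptake` is the
// uptake-rate bound (positive magnitude) applied as lower bound
// -uptake[i,k] on exchange column ex_idx[k].  Returns the flux values of
// the columns in out_idx for every row, plus a status vector
// (0 = optimal, 1 = infeasible -> fluxes reported as zero).  Results are
// independent of the warm-start path because every stage is solved to the
// same optimality tolerance from a feasible basis.
//' @noRd
// [[Rcpp::export(name = ".lex_fba_batch_cpp")]]
List lex_fba_batch_cpp(NumericMatrix A, NumericVector lower,
                       NumericVector upper, IntegerVector ex_idx,
                       NumericMatrix uptake, IntegerVector obj_idx,
                       IntegerVector sense, IntegerVector out_idx,
                       int atpm_idx = -1, double atpm_demand = 0,
                       double fix_rtol = 1e-9, double fix_atol = 1e-12,
                       int maxit = 20000) {
  int N = uptake.nrow(), nex = ex_idx.size(), nout = out_idx.size();
  NumericMatrix out(N, nout);
  IntegerVector status(N);
  std::vector<double> lo0(lower.begin(), lower.end());
  std::vector<double> up0(upper.begin(), upper.end());
  BoundedLP lp;
  bool have_basis = false;
  std::vector<double> x;
  for (int i = 0; i < N; ++i) {
    std::vector<double> lo(lo0), up(up0);
    for (int k = 0; k < nex; ++k) {
      int j = ex_idx[k] - 1;
      lo[j] = -uptake(i, k);
      if (up[j] < lo[j]) up[j] = lo[j];
    }
    int st = lex_with_starvation(lp, have_basis, A, lo, up, obj_idx, sense,
                                 atpm_idx - 1, atpm_demand,
                                 fix_rtol, fix_atol, maxit, x);
    if (st == 0 || st == 2) {
      for (int k = 0; k < nout; ++k) out(i, k) = x[out_idx[k] - 1];
      status[i] = st;
    } else if (st == 1) {
      for (int k = 0; k < nout; ++k) out(i, k) = 0.0;
      status[i] = 1;
    } else {
      status[i] = st;
    }
  }
  return List::create(_["status"] = status, _["flux"] = out);
}
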