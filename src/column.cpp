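// Compiled column engine: kinetics, per-node lexicographic FBA with
// time-persistent warm-started bases, transport stencils, and the
// biological block of the banded Jacobian.  Mirrors the reference R
// implementation of the right-hand side (engine_rhs); the R path is kept
// as the readable specification and cross-checked in the test suite.

#include "lp.h"
using namespace syncol_lp;
#include <cstring>

namespace {

struct ColumnProblem {
  // LP data
  NumericMatrix A;
  std::vector<double> lo0, up0;
  std::vector<int> ex_idx;   // 0-based: co, h2, co2 exchange columns
  std::vector<int> obj_idx;  // 0-based objective columns
  std::vector<int> sense;    // +1 max, -1 min (signed flux)
  std::vector<int> out_idx;  // 0-based: mu, vC, vH, vD, vE, vA
  double fix_rtol, fix_atol;
  int maxit;
  int atpm_idx;          // 0-based maintenance column
  double atpm_demand;
  // kinetics
  double vmax[3], Km[3], KI, KIC, KIH;
  bool co_inhib;
  double mw_co;
  // transport
  int N;
  double dz, uLe, uGe, DA, eps_L, eps_G;
  double km[3], hf[3], feed[3];
  double beta;          // Danckwerts ghost coefficient
  bool third_order;
  IntegerVector obj1, sen1;  // 1-based objective spec for the LP driver
  double mwE, mwA;
  // persistent per-node solver states (rhs path and jacobian path)
  std::vector<BoundedLP> lps, lps_jac;
  std::vector<char> have, have_jac;
};

// uptake bounds with the C1 regularization factor S/(S + delta) that
// removes the Monod kink at zero concentration (delta = 1e-6 mmol/L)
const double UPTAKE_DELTA = 1e-6;

void node_bounds(const ColumnProblem &p, double CL, double HL, double DL,
                 double E, double A_, double *b) {
  double inhib = 1.0 / (1.0 + (E + A_) / p.KI);
  double rC = CL / (CL + UPTAKE_DELTA), rH = HL / (HL + UPTAKE_DELTA),
         rD = DL / (DL + UPTAKE_DELTA);
  if (p.co_inhib) {
    double C_gL = CL * p.mw_co / 1000.0;
    b[0] = p.vmax[0] * CL / (p.Km[0] + CL + CL * C_gL / p.KIC) * inhib * rC;
    b[1] = p.vmax[1] * HL / (p.Km[1] + HL) * inhib /
           (1.0 + C_gL / p.KIH) * rH;
  } else {
    b[0] = p.vmax[0] * CL / (p.Km[0] + CL) * inhib * rC;
    b[1] = p.vmax[1] * HL / (p.Km[1] + HL) * inhib * rH;
  }
  b[2] = p.vmax[2] * DL / (p.Km[2] + DL) * inhib * rD;
}

// lexicographic solve for one node with its own persistent warm basis
int node_solve(ColumnProblem &p, BoundedLP &lp, char &have,
               const double *ub3, double *fluxout) {
  std::vector<double> lo(p.lo0), up(p.up0);
  for (int k = 0; k < 3; ++k) {
    int j = p.ex_idx[k];
    lo[j] = -ub3[k];
    if (up[j] < lo[j]) up[j] = lo[j];
  }
  bool hb = have != 0;
  std::vector<double> x;
  int st = lex_with_starvation(lp, hb, p.A, lo, up, p.obj1, p.sen1,
                               p.atpm_idx, p.atpm_demand,
                               p.fix_rtol, p.fix_atol, p.maxit, x);
  have = hb ? 1 : 0;
  if (st == 0 || st == 2) {
    for (int k = 0; k < 6; ++k) fluxout[k] = x[p.out_idx[k]];
  } else if (st == 1) {
    for (int k = 0; k < 6; ++k) fluxout[k] = 0.0;
  }
  return st;
}

// solve all nodes from the clipped concentration fields (column-major
// conc: CL, HL, DL, EL, AL each length N); flux: N x 6 column-major
int solve_column(ColumnProblem &p, std::vector<BoundedLP> &lps,
                 std::vector<char> &have, const double *CL, const double *HL,
                 const double *DL, const double *EL, const double *AL,
                 double *flux, int *status) {
  double b[3], f[6];
  for (int i = 0; i < p.N; ++i) {
    node_bounds(p, CL[i], HL[i], DL[i], EL[i], AL[i], b);
    int st = node_solve(p, lps[i], have[i], b, f);
    if (st > 2) return st;
    if (status) status[i] = st;
    for (int k = 0; k < 6; ++k) flux[k * p.N + i] = f[k];
  }
  return 0;
}

inline double clip0(double v) { return v > 0.0 ? v : 0.0; }

// transport operators; fields are length-N contiguous
void conv_upwind(const ColumnProblem &p, const double *f, double ghost0,
                 double *d) {
  int N = p.N; double dz = p.dz;
  d[0] = (f[0] - ghost0) / dz;
  d[1] = (f[1] - f[0]) / dz;
  d[N - 1] = (f[N - 1] - f[N - 2]) / dz;
  if (p.third_order) {
    for (int j = 2; j < N - 1; ++j)
      d[j] = (2.0 * f[j + 1] + 3.0 * f[j] - 6.0 * f[j - 1] + f[j - 2]) /
             (6.0 * dz);
  } else {
    for (int j = 2; j < N - 1; ++j) d[j] = (f[j] - f[j - 1]) / dz;
  }
}

void disp_central(const ColumnProblem &p, const double *f, double ghost0,
                  double *d) {
  int N = p.N; double dz2 = p.dz * p.dz;
  d[0] = (ghost0 - 2.0 * f[0] + f[1]) / dz2;
  for (int j = 1; j < N - 1; ++j)
    d[j] = (f[j - 1] - 2.0 * f[j] + f[j + 1]) / dz2;
  d[N - 1] = 2.0 * (f[N - 2] - f[N - 1]) / dz2;
}

// dy and flux are preallocated; returns 0 / infeasible handled inside
int column_rhs_core(ColumnProblem &p, const double *y, double *dy,
                    double *flux) {
  int N = p.N;
  std::vector<double> fld(9 * N), cl(5 * N);
  // de-interleave
  for (int j = 0; j < N; ++j)
    for (int k = 0; k < 9; ++k) fld[k * N + j] = y[j * 9 + k];
  const double *X = &fld[0], *CL = &fld[N], *HL = &fld[2 * N],
               *DL = &fld[3 * N], *EL = &fld[4 * N], *AL = &fld[5 * N],
               *CG = &fld[6 * N], *HG = &fld[7 * N], *DG = &fld[8 * N];
  for (int j = 0; j < N; ++j) {
    cl[j] = clip0(CL[j]); cl[N + j] = clip0(HL[j]);
    cl[2 * N + j] = clip0(DL[j]); cl[3 * N + j] = clip0(EL[j]);
    cl[4 * N + j] = clip0(AL[j]);
  }
  int st = solve_column(p, p.lps, p.have, &cl[0], &cl[N], &cl[2 * N],
                        &cl[3 * N], &cl[4 * N], flux, nullptr);
  if (st > 1) return st;
  const double *mu = &flux[0], *vC = &flux[N], *vH = &flux[2 * N],
               *vD = &flux[3 * N], *vE = &flux[4 * N], *vA = &flux[5 * N];
  std::vector<double> conv(N), disp(N), tr(3 * N);
  for (int j = 0; j < N; ++j) {
    tr[j] = p.km[0] * (p.hf[0] * CG[j] - CL[j]);
    tr[N + j] = p.km[1] * (p.hf[1] * HG[j] - HL[j]);
    tr[2 * N + j] = p.km[2] * (p.hf[2] * DG[j] - DL[j]);
  }
  // liquid fields
  const double *liq[6] = {X, CL, HL, DL, EL, AL};
  for (int k = 0; k < 6; ++k) {
    const double *f = liq[k];
    double ghost0 = f[1] - p.beta * f[0];  // Danckwerts, zero feed
    conv_upwind(p, f, ghost0, &conv[0]);
    disp_central(p, f, ghost0, &disp[0]);
    for (int j = 0; j < N; ++j) {
      double src = 0.0, Xc = clip0(X[j]);
      switch (k) {
        case 0: src = mu[j] * Xc; break;
        case 1: src = vC[j] * Xc + tr[j] / p.eps_L; break;
        case 2: src = vH[j] * Xc + tr[N + j] / p.eps_L; break;
        case 3: src = vD[j] * Xc + tr[2 * N + j] / p.eps_L; break;
        case 4: src = p.mwE * vE[j] * Xc; break;
        case 5: src = p.mwA * vA[j] * Xc; break;
      }
      dy[j * 9 + k] = src - p.uLe * conv[j] + p.DA * disp[j];
    }
  }
  // gas fields: pure convection, Dirichlet inlet
  const double *gasf[3] = {CG, HG, DG};
  for (int k = 0; k < 3; ++k) {
    conv_upwind(p, gasf[k], p.feed[k], &conv[0]);
    for (int j = 0; j < N; ++j)
      dy[j * 9 + 6 + k] = -tr[k * N + j] / p.eps_G - p.uGe * conv[j];
    dy[6 + k] = 0.0;  // inlet node pinned to feed
  }
  return 0;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".column_engine_new")]]
SEXP column_engine_new(NumericMatrix A, NumericVector lower,
                       NumericVector upper, IntegerVector ex_idx,
                       IntegerVector obj_idx, IntegerVector sense,
                       IntegerVector out_idx, List kinetics, List transport,
                       int atpm_idx, double atpm_demand,
                       double fix_rtol, double fix_atol, int maxit) {
  ColumnProblem *p = new ColumnProblem();
  p->A = A;
  p->lo0.assign(lower.begin(), lower.end());
  p->up0.assign(upper.begin(), upper.end());
  for (int k = 0; k < ex_idx.size(); ++k) p->ex_idx.push_back(ex_idx[k] - 1);
  for (int k = 0; k < obj_idx.size(); ++k) {
    p->obj_idx.push_back(obj_idx[k] - 1);
    p->sense.push_back(sense[k]);
  }
  p->obj1 = clone(obj_idx); p->sen1 = clone(sense);
  for (int k = 0; k < out_idx.size(); ++k) p->out_idx.push_back(out_idx[k] - 1);
  p->fix_rtol = fix_rtol; p->fix_atol = fix_atol; p->maxit = maxit;
  p->atpm_idx = atpm_idx - 1; p->atpm_demand = atpm_demand;
  NumericVector vmax = kinetics["v_max"], Kms = kinetics["K_m"];
  for (int k = 0; k < 3; ++k) { p->vmax[k] = vmax[k]; p->Km[k] = Kms[k]; }
  p->KI = as<double>(kinetics["K_I"]);
  p->KIC = as<double>(kinetics["K_I_C"]);
  p->KIH = as<double>(kinetics["K_I_H"]);
  p->co_inhib = as<bool>(kinetics["co_inhibition"]);
  p->mw_co = as<double>(kinetics["mw_co"]);
  p->N = as<int>(transport["N"]);
  p->dz = as<double>(transport["dz"]);
  p->uLe = as<double>(transport["uLe"]);
  p->uGe = as<double>(transport["uGe"]);
  p->DA = as<double>(transport["DA"]);
  p->eps_L = as<double>(transport["eps_L"]);
  p->eps_G = as<double>(transport["eps_G"]);
  NumericVector km = transport["km"], hf = transport["hf"],
               feed = transport["feed"];
  for (int k = 0; k < 3; ++k) {
    p->km[k] = km[k]; p->hf[k] = hf[k]; p->feed[k] = feed[k];
  }
  p->beta = as<double>(transport["beta"]);
  p->third_order = as<bool>(transport["third_order"]);
  p->mwE = as<double>(transport["M_E"]);
  p->mwA = as<double>(transport["M_A"]);
  p->lps.resize(p->N); p->lps_jac.resize(p->N);
  p->have.assign(p->N, 0); p->have_jac.assign(p->N, 0);
  XPtr<ColumnProblem> ptr(p, true);
  return ptr;
}

//' @noRd
// [[Rcpp::export(name = ".column_rhs_cpp")]]
List column_rhs_cpp(SEXP engine, double t, NumericVector y,
                    bool want_flux = false) {
  XPtr<ColumnProblem> p(engine);
  int N = p->N;
  NumericVector dy(9 * N);
  std::vector<double> flux(6 * N);
  int st = column_rhs_core(*p, y.begin(), dy.begin(), &flux[0]);
  if (st > 2) stop("LP solver failed to converge in column RHS");
  for (int i = 0; i < 9 * N; ++i) {
    if (!R_finite(dy[i]))
      stop("non-finite derivative at node %d (t = %g h)", i / 9 + 1, t);
  }
  if (!want_flux) return List::create(dy);
  NumericMatrix fm(N, 6);
  std::memcpy(fm.begin(), &flux[0], sizeof(double) * 6 * N);
  colnames(fm) = CharacterVector::create("mu", "v_co", "v_h2", "v_co2",
                                         "v_etoh", "v_ac");
  return List::create(_["dy"] = dy, _["flux"] = fm);
}

// packed banded Jacobian: copies the precomputed linear part and adds the
// biological block from one-sided differences of the per-node LP solves.
//' @noRd
// [[Rcpp::export(name = ".column_jac_cpp")]]
NumericMatrix column_jac_cpp(SEXP engine, double t, NumericVector y,
                             NumericMatrix base, int bandup) {
  XPtr<ColumnProblem> p(engine);
  int N = p->N, nb = base.nrow();
  NumericMatrix pack = clone(base);
  std::vector<double> cl(5 * N), flux0(6 * N), fluxp(6 * N);
  std::vector<double> Xc(N);
  for (int j = 0; j < N; ++j) {
    Xc[j] = clip0(y[j * 9]);
    for (int k = 0; k < 5; ++k) cl[k * N + j] = clip0(y[j * 9 + 1 + k]);
  }
  int st = solve_column(*p, p->lps_jac, p->have_jac, &cl[0], &cl[N],
                        &cl[2 * N], &cl[3 * N], &cl[4 * N], &flux0[0],
                        nullptr);
  if (st > 2) stop("LP solver failed in Jacobian evaluation");
  double wt[6] = {1.0, 1.0, 1.0, 1.0, p->mwE, p->mwA};
  // X column: source terms are flux * X
  for (int j = 0; j < N; ++j) {
    int col = j * 9;  // 0-based column of X at node j
    for (int k = 0; k < 6; ++k) {
      int row = bandup + k;  // eq (j*9+k) - var (j*9) + bandup
      pack(row, col) += wt[k] * flux0[k * N + j];
    }
  }
  std::vector<double> clp(5 * N);
  for (int i = 0; i < 5; ++i) {  // CL HL DL EL AL columns
    std::copy(cl.begin(), cl.end(), clp.begin());
    std::vector<double> h(N);
    for (int j = 0; j < N; ++j) {
      double s = cl[i * N + j] > 1e-3 ? cl[i * N + j] : 1e-3;
      h[j] = 1e-6 * s;
      clp[i * N + j] = cl[i * N + j] + h[j];
    }
    st = solve_column(*p, p->lps_jac, p->have_jac, &clp[0], &clp[N],
                      &clp[2 * N], &clp[3 * N], &clp[4 * N], &fluxp[0],
                      nullptr);
    if (st > 2) stop("LP solver failed in Jacobian evaluation");
    for (int j = 0; j < N; ++j) {
      int col = j * 9 + 1 + i;
      for (int k = 0; k < 6; ++k) {
        int row = bandup + k - (1 + i);
        double d = (fluxp[k * N + j] - flux0[k * N + j]) / h[j];
        pack(row, col) += wt[k] * Xc[j] * d;
      }
    }
  }
  return pack;
}

//' @noRd
// [[Rcpp::export(name = ".column_engine_reset")]]
void column_engine_reset(SEXP engine) {
  XPtr<ColumnProblem> p(engine);
  std::fill(p->have.begin(), p->have.end(), 0);
  std::fill(p->have_jac.begin(), p->have_jac.end(), 0);
}
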