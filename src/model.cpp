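// Core numerics for the G0/G1 -> S switch model: right-hand sides, analytic
// Jacobians, an adaptive BDF(1,2) integrator for the stiff system, and a
// damped-Newton equilibrium refiner.  All routines take the parameter vector
// in the canonical order defined by param_names() on the R side; the enum
// below must stay in sync with it.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

enum Par {
  KS_MAFF, KS_EGR3, KS_CD, KS_CE, KS_E2F, KS_RB, KS_P18, KS_P19,
  KD_MF, KD_EG, KD_CD, KD_CE, KD_E2F, KD_RB, KD_P18, KD_P19,
  KP_CD, KP_CE,
  K_ECD, K_EG_CD, K_I18, K_I19, K_I16, K_ECE, K_EG_CE, K_MF_CE,
  K_I21, K_I27, K_EE, K_RB_E2F, K_PRB, K_E18, K_EG18, K_MF_P18, K_E19, K_EG19,
  A_ECD, E0, E_AUTO, B18, A_E18, B19, A_E19, G_EG18, G_EG19,
  ALPHA16, ALPHA18, ALPHA19, ALPHA21, ALPHA27, BETA,
  GF, P53_0, AKT_0, P16_0, P21_BASE, P27_BASE, BETA53, K53, K_AKT,
  N_PAR
};

// species indices (order of SpeciesState)
enum Sp { iMF, iEG, iCD, iCE, iE2F, iRB, iP18, iP19, N_SP };

// hypothesis actions (regulatory code digits)
enum Act { INHIB = 1, NONE = 2, ACTIV = 3 };

static inline double hillA(double x, double K) { return x / (K + x); }
static inline double hillI(double x, double K) { return K / (K + x); }
// d/dx of hillA; d/dx hillI = -dA
static inline double dhillA(double x, double K) {
  const double s = K + x;
  return K / (s * s);
}

// edge modifier M(x; action, K) and its derivative
static inline double edgeM(double x, int act, double K, double beta) {
  if (act == ACTIV) return 1.0 + beta * hillA(x, K);
  if (act == INHIB) return hillI(x, K);
  return 1.0;
}
static inline double dedgeM(double x, int act, double K, double beta) {
  if (act == ACTIV) return beta * dhillA(x, K);
  if (act == INHIB) return -dhillA(x, K);
  return 0.0;
}

struct Sys {
  arma::vec p;   // N_PAR parameters
  int h[4];      // code digits: Maff->Cdk2, Maff->p18, Egr3->Cdk2, Egr3->Cdk4/6
  double P21, P27;  // derived quasi-static pools
};

static Sys make_sys(const arma::vec& par, const arma::ivec& hyp) {
  if ((int)par.n_elem != N_PAR) stop("parameter vector must have %d entries", (int)N_PAR);
  if (hyp.n_elem != 4) stop("hypothesis must have 4 digits");
  Sys s;
  s.p = par;
  for (int k = 0; k < 4; ++k) {
    s.h[k] = hyp[k];
    if (s.h[k] < 1 || s.h[k] > 3) stop("hypothesis digits must be 1, 2 or 3");
  }
  const arma::vec& p = s.p;
  s.P21 = p[P21_BASE] * (1.0 + p[BETA53] * hillA(p[P53_0], p[K53]));
  s.P27 = p[P27_BASE] * hillI(p[AKT_0], p[K_AKT]);
  return s;
}

// Nonlinear (Hill) terms see the state clamped at zero so a transient solver
// under-shoot cannot cross a Hill pole; linear decay terms keep the raw value
// so negativity self-corrects.
static arma::vec rhs_(const Sys& s, const arma::vec& x) {
  const arma::vec& p = s.p;
  arma::vec xa = arma::clamp(x, 0.0, arma::datum::inf);
  const double MF = xa[iMF], EG = xa[iEG], CD = xa[iCD], CE = xa[iCE];
  const double E2F = xa[iE2F], RB = xa[iRB], P18 = xa[iP18], P19 = xa[iP19];
  const double beta = p[BETA];

  arma::vec f(N_SP);
  f[iMF] = p[KS_MAFF] - p[KD_MF] * x[iMF];
  f[iEG] = p[KS_EGR3] - p[KD_EG] * x[iEG];

  const double deg_cd = 1.0 + p[ALPHA18] * hillA(P18, p[K_I18]) +
                        p[ALPHA19] * hillA(P19, p[K_I19]) +
                        p[ALPHA16] * hillA(p[P16_0], p[K_I16]);
  f[iCD] = p[KS_CD] * (p[GF] + p[A_ECD] * hillA(E2F, p[K_ECD])) *
             edgeM(EG, s.h[3], p[K_EG_CD], beta) -
           p[KD_CD] * x[iCD] * deg_cd;

  const double deg_ce = 1.0 + p[ALPHA21] * hillA(s.P21, p[K_I21]) +
                        p[ALPHA27] * hillA(s.P27, p[K_I27]);
  f[iCE] = p[KS_CE] * hillA(E2F, p[K_ECE]) *
             edgeM(EG, s.h[2], p[K_EG_CE], beta) *
             edgeM(MF, s.h[0], p[K_MF_CE], beta) -
           p[KD_CE] * x[iCE] * deg_ce;

  f[iE2F] = p[KS_E2F] * (p[E0] + p[E_AUTO] * hillA(E2F, p[K_EE])) *
              hillI(RB, p[K_RB_E2F]) -
            p[KD_E2F] * x[iE2F];

  f[iRB] = p[KS_RB] -
           (p[KP_CD] * CD + p[KP_CE] * CE) * hillA(RB, p[K_PRB]) -
           p[KD_RB] * x[iRB];

  f[iP18] = p[KS_P18] * (p[B18] + p[A_E18] * hillA(E2F, p[K_E18])) *
              (1.0 + p[G_EG18] * hillA(EG, p[K_EG18])) *
              edgeM(MF, s.h[1], p[K_MF_P18], beta) -
            p[KD_P18] * x[iP18];

  f[iP19] = p[KS_P19] * (p[B19] + p[A_E19] * hillA(E2F, p[K_E19])) *
              (1.0 + p[G_EG19] * hillA(EG, p[K_EG19])) -
            p[KD_P19] * x[iP19];
  return f;
}

static arma::mat jac_(const Sys& s, const arma::vec& x) {
  const arma::vec& p = s.p;
  arma::vec xa = arma::clamp(x, 0.0, arma::datum::inf);
  const double MF = xa[iMF], EG = xa[iEG], CD = xa[iCD], CE = xa[iCE];
  const double E2F = xa[iE2F], RB = xa[iRB], P18 = xa[iP18], P19 = xa[iP19];
  const double beta = p[BETA];
  // clamped coordinates contribute zero slope through Hill terms
  auto gate = [&](int i) { return x[i] > 0.0 ? 1.0 : 0.0; };

  arma::mat J(N_SP, N_SP, arma::fill::zeros);
  J(iMF, iMF) = -p[KD_MF];
  J(iEG, iEG) = -p[KD_EG];

  const double deg_cd = 1.0 + p[ALPHA18] * hillA(P18, p[K_I18]) +
                        p[ALPHA19] * hillA(P19, p[K_I19]) +
                        p[ALPHA16] * hillA(p[P16_0], p[K_I16]);
  const double syn_cd_e = p[GF] + p[A_ECD] * hillA(E2F, p[K_ECD]);
  const double m4 = edgeM(EG, s.h[3], p[K_EG_CD], beta);
  J(iCD, iE2F) = p[KS_CD] * p[A_ECD] * dhillA(E2F, p[K_ECD]) * m4 * gate(iE2F);
  J(iCD, iEG) = p[KS_CD] * syn_cd_e * dedgeM(EG, s.h[3], p[K_EG_CD], beta) * gate(iEG);
  J(iCD, iCD) = -p[KD_CD] * deg_cd;
  J(iCD, iP18) = -p[KD_CD] * x[iCD] * p[ALPHA18] * dhillA(P18, p[K_I18]) * gate(iP18);
  J(iCD, iP19) = -p[KD_CD] * x[iCD] * p[ALPHA19] * dhillA(P19, p[K_I19]) * gate(iP19);

  const double deg_ce = 1.0 + p[ALPHA21] * hillA(s.P21, p[K_I21]) +
                        p[ALPHA27] * hillA(s.P27, p[K_I27]);
  const double m3 = edgeM(EG, s.h[2], p[K_EG_CE], beta);
  const double m1 = edgeM(MF, s.h[0], p[K_MF_CE], beta);
  J(iCE, iE2F) = p[KS_CE] * dhillA(E2F, p[K_ECE]) * m3 * m1 * gate(iE2F);
  J(iCE, iEG) = p[KS_CE] * hillA(E2F, p[K_ECE]) *
                dedgeM(EG, s.h[2], p[K_EG_CE], beta) * m1 * gate(iEG);
  J(iCE, iMF) = p[KS_CE] * hillA(E2F, p[K_ECE]) * m3 *
                dedgeM(MF, s.h[0], p[K_MF_CE], beta) * gate(iMF);
  J(iCE, iCE) = -p[KD_CE] * deg_ce;

  J(iE2F, iE2F) = p[KS_E2F] * p[E_AUTO] * dhillA(E2F, p[K_EE]) *
                    hillI(RB, p[K_RB_E2F]) * gate(iE2F) -
                  p[KD_E2F];
  J(iE2F, iRB) = -p[KS_E2F] * (p[E0] + p[E_AUTO] * hillA(E2F, p[K_EE])) *
                 dhillA(RB, p[K_RB_E2F]) * gate(iRB);

  const double aprb = hillA(RB, p[K_PRB]);
  J(iRB, iCD) = -p[KP_CD] * aprb * gate(iCD);
  J(iRB, iCE) = -p[KP_CE] * aprb * gate(iCE);
  J(iRB, iRB) = -(p[KP_CD] * CD + p[KP_CE] * CE) * dhillA(RB, p[K_PRB]) * gate(iRB) -
                p[KD_RB];

  const double e18 = p[B18] + p[A_E18] * hillA(E2F, p[K_E18]);
  const double g18 = 1.0 + p[G_EG18] * hillA(EG, p[K_EG18]);
  const double m2 = edgeM(MF, s.h[1], p[K_MF_P18], beta);
  J(iP18, iE2F) = p[KS_P18] * p[A_E18] * dhillA(E2F, p[K_E18]) * g18 * m2 * gate(iE2F);
  J(iP18, iEG) = p[KS_P18] * e18 * p[G_EG18] * dhillA(EG, p[K_EG18]) * m2 * gate(iEG);
  J(iP18, iMF) = p[KS_P18] * e18 * g18 *
                 dedgeM(MF, s.h[1], p[K_MF_P18], beta) * gate(iMF);
  J(iP18, iP18) = -p[KD_P18];

  const double e19 = p[B19] + p[A_E19] * hillA(E2F, p[K_E19]);
  const double g19 = 1.0 + p[G_EG19] * hillA(EG, p[K_EG19]);
  J(iP19, iE2F) = p[KS_P19] * p[A_E19] * dhillA(E2F, p[K_E19]) * g19 * gate(iE2F);
  J(iP19, iEG) = p[KS_P19] * e19 * p[G_EG19] * dhillA(EG, p[K_EG19]) * gate(iEG);
  J(iP19, iP19) = -p[KD_P19];
  return J;
}

// synthesis (first) term of every ODE, the gene-expression surrogate
static arma::vec syn_(const Sys& s, const arma::vec& x) {
  const arma::vec& p = s.p;
  arma::vec xa = arma::clamp(x, 0.0, arma::datum::inf);
  const double MF = xa[iMF], EG = xa[iEG], E2F = xa[iE2F], RB = xa[iRB];
  const double beta = p[BETA];
  arma::vec v(N_SP);
  v[iMF] = p[KS_MAFF];
  v[iEG] = p[KS_EGR3];
  v[iCD] = p[KS_CD] * (p[GF] + p[A_ECD] * hillA(E2F, p[K_ECD])) *
           edgeM(EG, s.h[3], p[K_EG_CD], beta);
  v[iCE] = p[KS_CE] * hillA(E2F, p[K_ECE]) *
           edgeM(EG, s.h[2], p[K_EG_CE], beta) *
           edgeM(MF, s.h[0], p[K_MF_CE], beta);
  v[iE2F] = p[KS_E2F] * (p[E0] + p[E_AUTO] * hillA(E2F, p[K_EE])) *
            hillI(RB, p[K_RB_E2F]);
  v[iRB] = p[KS_RB];
  v[iP18] = p[KS_P18] * (p[B18] + p[A_E18] * hillA(E2F, p[K_E18])) *
            (1.0 + p[G_EG18] * hillA(EG, p[K_EG18])) *
            edgeM(MF, s.h[1], p[K_MF_P18], beta);
  v[iP19] = p[KS_P19] * (p[B19] + p[A_E19] * hillA(E2F, p[K_E19])) *
            (1.0 + p[G_EG19] * hillA(EG, p[K_EG19]));
  return v;
}

// [[Rcpp::export]]
arma::vec cc_rhs(const arma::vec& par, const arma::ivec& hyp, const arma::vec& x) {
  return rhs_(make_sys(par, hyp), x);
}

// [[Rcpp::export]]
arma::mat cc_jac(const arma::vec& par, const arma::ivec& hyp, const arma::vec& x) {
  return jac_(make_sys(par, hyp), x);
}

// [[Rcpp::export]]
arma::vec cc_synthesis(const arma::vec& par, const arma::ivec& hyp, const arma::vec& x) {
  return syn_(make_sys(par, hyp), x);
}

// [[Rcpp::export]]
NumericVector cc_static_pools(const arma::vec& par) {
  Sys s = make_sys(par, arma::ivec{2, 2, 2, 2});
  return NumericVector::create(_["P21"] = s.P21, _["P27"] = s.P27);
}

// ---------------------------------------------------------------------------
// implicit step solve: x - bh*f(x) = c, Newton with analytic Jacobian
static bool implicit_solve(const Sys& s, arma::vec& x, const arma::vec& c,
                           double bh, const arma::vec& wt) {
  for (int it = 0; it < 12; ++it) {
    arma::vec g = x - bh * rhs_(s, x) - c;
    if (arma::norm(g / wt, "inf") < 1e-3) {  // wt-scaled Newton tolerance
      return true;
    }
    arma::mat J = arma::eye(N_SP, N_SP) - bh * jac_(s, x);
    arma::vec dx;
    if (!arma::solve(dx, J, -g, arma::solve_opts::no_approx)) return false;
    x += dx;
    if (!x.is_finite()) return false;
  }
  return false;
}

static double err_norm(const arma::vec& e, const arma::vec& wt) {
  return arma::norm(e / wt, 2) / std::sqrt((double)N_SP);
}

struct StepResult {
  arma::vec x_end, x90;
  int n_accept = 0, n_reject = 0;
  int status = 0;  // 0 ok, 1 step underflow, 2 max steps
  double t_reached = 0.0;
};

// adaptive BDF1/BDF2 from 0 to t_end; optionally record accepted steps
static StepResult integrate_(const Sys& s, arma::vec x0, double t_end,
                             double rtol, double atol, int max_steps,
                             std::vector<double>* ts, std::vector<arma::vec>* xs) {
  StepResult out;
  double t = 0.0;
  arma::vec x = x0, x_prev = x0;
  double h_prev = 0.0;
  // initial step from the rhs magnitude
  arma::vec f0 = rhs_(s, x0);
  double scale = arma::norm(f0, "inf");
  double h = (scale > 0) ? std::min(1e-2 / scale, t_end / 100.0) : t_end / 100.0;
  h = std::max(h, t_end * 1e-10);
  bool have_hist = false;
  out.x90 = x0;
  if (ts) { ts->push_back(0.0); xs->push_back(x0); }

  while (t < t_end) {
    if (out.n_accept + out.n_reject > max_steps) { out.status = 2; break; }
    h = std::min(h, t_end - t);
    arma::vec wt = atol + rtol * arma::abs(x);
    arma::vec x_new, x_pred;
    double err;
    int order;
    if (!have_hist) {
      order = 1;
      x_pred = x + h * rhs_(s, x);
      x_new = x_pred;
      if (!implicit_solve(s, x_new, x, h, wt)) {
        h *= 0.3; ++out.n_reject;
        if (h < t_end * 1e-13) { out.status = 1; break; }
        continue;
      }
      err = 0.5 * err_norm(x_new - x_pred, wt);
    } else {
      order = 2;
      const double rho = h / h_prev;
      const double d = 1.0 + 2.0 * rho;
      const double a1 = (1.0 + rho) * (1.0 + rho) / d;
      const double a2 = -rho * rho / d;
      const double b = h * (1.0 + rho) / d;
      arma::vec c = a1 * x + a2 * x_prev;
      x_pred = x + rho * (x - x_prev);  // linear extrapolation predictor
      x_new = x_pred;
      if (!implicit_solve(s, x_new, c, b, wt)) {
        h *= 0.3; ++out.n_reject; have_hist = false;
        if (h < t_end * 1e-13) { out.status = 1; break; }
        continue;
      }
      err = err_norm(x_new - x_pred, wt) / (1.0 + rho);
    }
    if (err <= 1.0) {
      x_prev = x; h_prev = h;
      x = x_new; t += h;
      have_hist = true;
      ++out.n_accept;
      if (t <= 0.9 * t_end) out.x90 = x;
      if (ts) { ts->push_back(t); xs->push_back(x); }
      double fac = 0.9 * std::pow(std::max(err, 1e-10), -1.0 / (order + 1));
      h *= std::min(4.0, std::max(0.3, fac));
    } else {
      ++out.n_reject;
      double fac = 0.9 * std::pow(err, -1.0 / (order + 1));
      h *= std::min(0.9, std::max(0.1, fac));
      if (h < t_end * 1e-13) { out.status = 1; break; }
    }
  }
  out.x_end = x;
  out.t_reached = t;
  return out;
}

// [[Rcpp::export]]
List cc_integrate(const arma::vec& par, const arma::ivec& hyp, const arma::vec& x0,
                  double t_end, double rtol, double atol, int max_steps) {
  Sys s = make_sys(par, hyp);
  std::vector<double> ts;
  std::vector<arma::vec> xs;
  StepResult r = integrate_(s, x0, t_end, rtol, atol, max_steps, &ts, &xs);
  arma::mat states(xs.size(), N_SP);
  for (size_t i = 0; i < xs.size(); ++i) states.row(i) = xs[i].t();
  return List::create(_["times"] = ts, _["states"] = states,
                      _["x90"] = r.x90, _["n_accept"] = r.n_accept,
                      _["n_reject"] = r.n_reject, _["status"] = r.status,
                      _["t_reached"] = r.t_reached);
}

// [[Rcpp::export]]
List cc_settle(const arma::vec& par, const arma::ivec& hyp, const arma::vec& x0,
               double t_end, double rtol, double atol, int max_steps) {
  Sys s = make_sys(par, hyp);
  StepResult r = integrate_(s, x0, t_end, rtol, atol, max_steps, nullptr, nullptr);
  return List::create(_["x_end"] = r.x_end, _["x90"] = r.x90,
                      _["n_accept"] = r.n_accept, _["status"] = r.status);
}

// damped Newton (Levenberg fallback + backtracking) for f(x) = 0, x >= 0
static List newton_(const Sys& s, arma::vec x, double tol, int max_iter) {
  x = arma::clamp(x, 0.0, arma::datum::inf);
  arma::vec f = rhs_(s, x);
  double best_res = arma::norm(f, "inf");
  arma::vec best_x = x;
  int it = 0;
  for (; it < max_iter; ++it) {
    double res = arma::norm(f, "inf");
    if (res < best_res) { best_res = res; best_x = x; }
    if (res <= tol) break;
    arma::mat J = jac_(s, x);
    arma::vec dx;
    if (!arma::solve(dx, J, -f, arma::solve_opts::no_approx)) {
      // singular Jacobian: Levenberg step
      arma::mat A = J.t() * J + 1e-8 * arma::eye(N_SP, N_SP);
      if (!arma::solve(dx, A, -J.t() * f, arma::solve_opts::no_approx)) break;
    }
    const double f2 = arma::dot(f, f);
    double step = 1.0;
    arma::vec x_try, f_try;
    bool ok = false;
    for (int ls = 0; ls < 30; ++ls) {
      x_try = arma::clamp(x + step * dx, 0.0, arma::datum::inf);
      f_try = rhs_(s, x_try);
      if (f_try.is_finite() && arma::dot(f_try, f_try) <= (1.0 - 1e-4 * step) * f2) {
        ok = true; break;
      }
      step *= 0.5;
    }
    if (!ok) break;  // stalled
    x = x_try; f = f_try;
  }
  double res = arma::norm(rhs_(s, x), "inf");
  if (res > best_res) { x = best_x; res = best_res; }
  return List::create(_["state"] = x, _["residual"] = res,
                      _["iterations"] = it, _["converged"] = res <= tol);
}

// [[Rcpp::export]]
List cc_newton(const arma::vec& par, const arma::ivec& hyp, const arma::vec& guess,
               double tol, int max_iter) {
  return newton_(make_sys(par, hyp), guess, tol, max_iter);
}

// settle-then-refine each start row; the multi-start equilibrium workhorse
// [[Rcpp::export]]
List cc_multistart(const arma::vec& par, const arma::ivec& hyp, const arma::mat& starts,
                   double t_settle, double rtol, double atol, int max_steps,
                   double newton_tol, int newton_max_iter) {
  Sys s = make_sys(par, hyp);
  const int n = starts.n_rows;
  arma::mat states(n, N_SP);
  arma::vec residuals(n);
  LogicalVector converged(n);
  for (int i = 0; i < n; ++i) {
    StepResult r = integrate_(s, starts.row(i).t(), t_settle, rtol, atol,
                              max_steps, nullptr, nullptr);
    List nw = newton_(s, r.x_end, newton_tol, newton_max_iter);
    arma::vec xe = nw["state"];
    states.row(i) = xe.t();
    residuals[i] = as<double>(nw["residual"]);
    converged[i] = as<bool>(nw["converged"]);
  }
  return List::create(_["states"] = states, _["residuals"] = residuals,
                      _["converged"] = converged);
}
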