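// Linear parent-metabolite compartmental engine.
//
// State layout (0-based), n = NTR + 6:
//   0 .. NTR-1   transit chain (dose target = state 0, or depot when NTR = 0)
//   NTR          depot (absorption compartment, rate KA into parent central)
//   NTR+1..NTR+3 parent central / peripheral 2 / peripheral 3
//   NTR+4..NTR+5 metabolite central / peripheral
//
// Amounts are tracked in parent-mass equivalents; fm * CL_P/V1_P of the
// parent elimination flow feeds the metabolite central compartment.
// Propagation is exact (matrix exponential) on every interval over which the
// clearance multipliers are constant; interval integrals of the state use
// solve(A, (expm(A dt) - I) x), valid because the system is strictly stable
// for positive eliminations.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// theta layout, fixed order shared with R (see THETA_ORDER in R/params.R):
// 0 MTT, 1 NTR, 2 KA, 3 CL_P, 4 V1_P, 5 V2_P, 6 V3_P, 7 Q2_P, 8 Q3_P,
// 9 CL_M, 10 V1_M, 11 V2_M, 12 Q_M, 13 F, 14 fm
static arma::mat rate_matrix_core(const arma::vec& th, double mp, double mm) {
  const int ntr = (int) std::lround(th(1));
  const int n = ntr + 6;
  const int dep = ntr, pc = ntr + 1, p2 = ntr + 2, p3 = ntr + 3,
            mc = ntr + 4, mper = ntr + 5;
  const double ktr = (ntr + 1.0) / th(0);
  const double clp = th(3) * mp, clm = th(9) * mm;
  const double v1p = th(4), v2p = th(5), v3p = th(6), q2 = th(7), q3 = th(8);
  const double v1m = th(10), v2m = th(11), qm = th(12), fm = th(14);
  arma::mat A(n, n, arma::fill::zeros);
  for (int i = 0; i < ntr; ++i) { A(i, i) -= ktr; A(i + 1, i) += ktr; }
  A(dep, dep) -= th(2);
  A(pc, dep)  += th(2);
  A(pc, pc)   -= (clp + q2 + q3) / v1p;
  A(p2, pc)   += q2 / v1p;  A(pc, p2) += q2 / v2p;  A(p2, p2) -= q2 / v2p;
  A(p3, pc)   += q3 / v1p;  A(pc, p3) += q3 / v3p;  A(p3, p3) -= q3 / v3p;
  A(mc, pc)   += fm * clp / v1p;
  A(mc, mc)   -= (clm + qm) / v1m;
  A(mper, mc) += qm / v1m;  A(mc, mper) += qm / v2m;  A(mper, mper) -= qm / v2m;
  return A;
}

// [[Rcpp::export]]
arma::mat rate_matrix_cpp(NumericVector theta, double mult_p, double mult_m) {
  return rate_matrix_core(as<arma::vec>(theta), mult_p, mult_m);
}

// Index of the multiplier interval containing time t: intervals are
// (-inf, sw[0]), [sw[0], sw[1]), ..., [sw[k-1], inf).
static int seg_index(double t, const arma::vec& sw) {
  int j = 0;
  for (arma::uword i = 0; i < sw.n_elem; ++i) if (t >= sw(i)) j = (int) i + 1;
  return j;
}

struct Engine {
  arma::vec th;
  arma::vec sw, mp, mm;
  std::vector<arma::mat> A;        // lazily built per segment
  std::vector<bool> have;
  Engine(const arma::vec& th_, const arma::vec& sw_, const arma::vec& mp_,
         const arma::vec& mm_)
      : th(th_), sw(sw_), mp(mp_), mm(mm_),
        A(sw_.n_elem + 1), have(sw_.n_elem + 1, false) {}
  const arma::mat& mat(int j) {
    if (!have[j]) { A[j] = rate_matrix_core(th, mp(j), mm(j)); have[j] = true; }
    return A[j];
  }
};

// Core sweep shared by profile and likelihood paths. Fills conc at obs_time
// (concentration recorded before any dose at the same timestamp) and, when
// want_auc, accumulates central-compartment integrals over [auc_from, auc_to].
static void sweep(Engine& eng,
                  const arma::vec& dose_time, const arma::vec& dose_amt,
                  const arma::vec& obs_time,
                  double auc_from, double auc_to, bool want_auc,
                  arma::vec& conc_p, arma::vec& conc_m,
                  double& auc_p, double& auc_m) {
  const int ntr = (int) std::lround(eng.th(1));
  const int n = ntr + 6, pc = ntr + 1, mc = ntr + 4;
  const double v1p = eng.th(4), v1m = eng.th(10), F = eng.th(13);
  auc_p = 0.0; auc_m = 0.0;
  conc_p.zeros(obs_time.n_elem); conc_m.zeros(obs_time.n_elem);
  if (dose_time.n_elem == 0) return;

  // checkpoints: every instant where something happens or is needed
  std::vector<double> cp(dose_time.begin(), dose_time.end());
  cp.insert(cp.end(), eng.sw.begin(), eng.sw.end());
  cp.insert(cp.end(), obs_time.begin(), obs_time.end());
  if (want_auc) {
    cp.push_back(auc_from);
    if (std::isfinite(auc_to)) cp.push_back(auc_to);
  }
  std::sort(cp.begin(), cp.end());
  cp.erase(std::unique(cp.begin(), cp.end()), cp.end());

  const double t0 = dose_time.min();
  arma::vec x(n, arma::fill::zeros);
  double t = t0;
  arma::uword iobs = 0;
  // observations strictly before the first dose are zero
  while (iobs < obs_time.n_elem && obs_time(iobs) < t0) ++iobs;

  for (double tc : cp) {
    if (tc < t0) continue;
    if (tc > t) {
      const double dt = tc - t;
      int j = seg_index(0.5 * (t + tc), eng.sw);
      const arma::mat& A = eng.mat(j);
      if (want_auc && t >= auc_from - 1e-12 &&
          (!std::isfinite(auc_to) || tc <= auc_to + 1e-12)) {
        // augmented exponential gives expm(A dt) and its integral at once,
        // valid for singular A as well
        arma::mat M(2 * n, 2 * n, arma::fill::zeros);
        M.submat(0, 0, n - 1, n - 1) = A;
        M.submat(0, n, n - 1, 2 * n - 1).eye();
        arma::mat E2 = arma::expmat(M * dt);
        arma::vec I = E2.submat(0, n, n - 1, 2 * n - 1) * x;
        auc_p += I(pc) / v1p;
        auc_m += I(mc) / v1m;
        x = E2.submat(0, 0, n - 1, n - 1) * x;
      } else {
        x = arma::expmat(A * dt) * x;
      }
      t = tc;
    }
    while (iobs < obs_time.n_elem && obs_time(iobs) == tc) {
      conc_p(iobs) = x(pc) / v1p;
      conc_m(iobs) = x(mc) / v1m;
      ++iobs;
    }
    for (arma::uword d = 0; d < dose_time.n_elem; ++d)
      if (dose_time(d) == tc) x(0) += dose_amt(d) * F;
  }
  if (want_auc && !std::isfinite(auc_to)) {
    int j = seg_index(t + 1.0, eng.sw);
    const arma::mat& A = eng.mat(j);
    // drop disconnected states (zero diagonal, no mass): keeps A invertible
    // for degenerate Q = 0 configurations while still rejecting genuinely
    // missing elimination pathways
    arma::uvec keep = arma::find(arma::abs(A.diag()) > 0.0 ||
                                 arma::abs(x) > 0.0);
    arma::mat Ak = A.submat(keep, keep);
    arma::vec xk = x.elem(keep);
    arma::vec Ik;
    bool ok = arma::solve(Ik, Ak, -xk, arma::solve_opts::no_approx);
    if (!ok) stop("infinite AUC undefined: system has a zero elimination rate");
    arma::vec I(n, arma::fill::zeros);
    I.elem(keep) = Ik;
    auc_p += I(pc) / v1p;
    auc_m += I(mc) / v1m;
  }
}

// [[Rcpp::export]]
List pk_profile_cpp(NumericVector theta,
                    NumericVector dose_time, NumericVector dose_amt,
                    NumericVector switch_time,
                    NumericVector mult_p, NumericVector mult_m,
                    NumericVector obs_time,
                    double auc_from, double auc_to, bool want_auc) {
  Engine eng(as<arma::vec>(theta), as<arma::vec>(switch_time),
             as<arma::vec>(mult_p), as<arma::vec>(mult_m));
  arma::vec cp, cm; double ap, am;
  sweep(eng, as<arma::vec>(dose_time), as<arma::vec>(dose_amt),
        as<arma::vec>(obs_time), auc_from, auc_to, want_auc, cp, cm, ap, am);
  return List::create(_["conc_parent"] = cp, _["conc_metab"] = cm,
                      _["auc_parent"] = ap, _["auc_metab"] = am);
}

// ---------------------------------------------------------------------------
// Mixed-effects machinery: per-subject conditional -2 log-likelihood and the
// Laplace-approximated marginal contribution.
//
// Random-effect slots (fixed meaning): 0 eta_CL_P, 1 eta_CL_M, 2 eta_IE_P,
// 3 eta_IE_M. `eta_idx` names the active subset (0-based), Omega is for that
// subset. IE multipliers apply on intervals flagged in `ie_active`.
// ---------------------------------------------------------------------------

struct SubjData {
  arma::vec th;                      // subject-level theta (allometry applied)
  double ie_p, ie_m;
  arma::vec dose_time, dose_amt, sw;
  arma::ivec ie_active;              // length sw + 1
  arma::vec obs_time; arma::ivec analyte; arma::vec y;
  double sig_p, sig_m;
};

// model predictions f at the observation times, given full 4-slot eta
static arma::vec predict_eta(const SubjData& d, const arma::vec& eta4) {
  arma::vec th = d.th;
  th(3) *= std::exp(eta4(0));
  th(9) *= std::exp(eta4(1));
  arma::vec mp(d.ie_active.n_elem), mm(d.ie_active.n_elem);
  for (arma::uword i = 0; i < d.ie_active.n_elem; ++i) {
    mp(i) = d.ie_active(i) ? d.ie_p * std::exp(eta4(2)) : 1.0;
    mm(i) = d.ie_active(i) ? d.ie_m * std::exp(eta4(3)) : 1.0;
  }
  Engine eng(th, d.sw, mp, mm);
  arma::vec cp, cm; double ap, am;
  sweep(eng, d.dose_time, d.dose_amt, d.obs_time, 0.0, 0.0, false, cp, cm, ap, am);
  arma::vec f(d.obs_time.n_elem);
  for (arma::uword i = 0; i < f.n_elem; ++i)
    f(i) = (d.analyte(i) == 1) ? cp(i) : cm(i);
  return f;
}

// conditional -2LL given predictions (proportional error); f <= 0 dropped
static double cond_m2ll(const SubjData& d, const arma::vec& f, int* ndrop) {
  double s = 0.0; int drop = 0;
  for (arma::uword i = 0; i < f.n_elem; ++i) {
    const double sig = (d.analyte(i) == 1) ? d.sig_p : d.sig_m;
    if (f(i) <= 0.0) { ++drop; continue; }
    const double v = sig * sig * f(i) * f(i);
    const double r = d.y(i) - f(i);
    s += std::log(2.0 * M_PI * v) + r * r / v;
  }
  if (ndrop) *ndrop = drop;
  return s;
}

static SubjData unpack(List subj, NumericVector theta, double ie_p, double ie_m,
                       double sig_p, double sig_m) {
  SubjData d;
  d.th = as<arma::vec>(theta);
  d.ie_p = ie_p; d.ie_m = ie_m; d.sig_p = sig_p; d.sig_m = sig_m;
  d.dose_time = as<arma::vec>(subj["dose_time"]);
  d.dose_amt  = as<arma::vec>(subj["dose_amt"]);
  d.sw        = as<arma::vec>(subj["switch_time"]);
  d.ie_active = as<arma::ivec>(subj["ie_active"]);
  d.obs_time  = as<arma::vec>(subj["obs_time"]);
  d.analyte   = as<arma::ivec>(subj["analyte"]);
  d.y         = as<arma::vec>(subj["y"]);
  return d;
}

// [[Rcpp::export]]
NumericVector cond_pred_cpp(List subj, NumericVector theta, double ie_p,
                            double ie_m, NumericVector eta4) {
  SubjData d = unpack(subj, theta, ie_p, ie_m, 0.1, 0.1);
  return wrap(predict_eta(d, eta4));
}

// gradient and Gauss-Newton Hessian of
//   h(eta) = 0.5 * cond_m2ll + 0.5 * eta' Oinv eta
// using finite-difference sensitivities J = df/deta (forward differences)
static void gn_parts(const SubjData& d, const arma::uvec& idx,
                     const arma::mat& Oinv, const arma::vec& eta,
                     const arma::vec& f0, arma::vec& g, arma::mat& H) {
  const arma::uword q = idx.n_elem, nobs = f0.n_elem;
  const double step = 1e-5;
  arma::mat J(nobs, q);
  for (arma::uword j = 0; j < q; ++j) {
    arma::vec e4(4, arma::fill::zeros);
    for (arma::uword k = 0; k < q; ++k) e4(idx(k)) = eta(k);
    e4(idx(j)) += step;
    J.col(j) = (predict_eta(d, e4) - f0) / step;
  }
  g = Oinv * eta;
  H = Oinv;
  for (arma::uword i = 0; i < nobs; ++i) {
    if (f0(i) <= 0.0) continue;
    const double sig = (d.analyte(i) == 1) ? d.sig_p : d.sig_m;
    const double f = f0(i), r = d.y(i) - f;
    const double s2 = sig * sig;
    const arma::vec Ji = J.row(i).t();
    // d/deta of 0.5*(log 2pi v + r^2/v), v = s2 f^2
    g += Ji * (1.0 / f - r / (s2 * f * f) - r * r / (s2 * f * f * f));
    // Fisher-information weight: f'^2/v + v'^2/(2 v^2)
    H += Ji * Ji.t() * (1.0 / (s2 * f * f) + 2.0 / (f * f));
  }
}

static double h_of(const SubjData& d, const arma::uvec& idx,
                   const arma::mat& Oinv, const arma::vec& eta,
                   arma::vec* f_out = nullptr) {
  arma::vec e4(4, arma::fill::zeros);
  for (arma::uword k = 0; k < idx.n_elem; ++k) e4(idx(k)) = eta(k);
  arma::vec f = predict_eta(d, e4);
  if (f_out) *f_out = f;
  return 0.5 * cond_m2ll(d, f, nullptr) +
         0.5 * arma::as_scalar(eta.t() * Oinv * eta);
}

// [[Rcpp::export]]
List laplace_subject_cpp(List subj, NumericVector theta, double ie_p,
                         double ie_m, double sig_p, double sig_m,
                         arma::mat Omega, IntegerVector eta_idx,
                         NumericVector eta_start, int maxit, double tol,
                         int hess_method) {
  SubjData d = unpack(subj, theta, ie_p, ie_m, sig_p, sig_m);
  arma::uvec idx = as<arma::uvec>(eta_idx);
  const arma::uword q = idx.n_elem;
  arma::mat Oinv = arma::inv_sympd(Omega);
  double ld_O, sgn; arma::log_det(ld_O, sgn, Omega);

  arma::vec eta = as<arma::vec>(eta_start);
  arma::vec f0;
  double h = h_of(d, idx, Oinv, eta, &f0);
  double lambda = 1e-3;
  bool conv = false;
  arma::vec g; arma::mat H;
  for (int it = 0; it < maxit; ++it) {
    gn_parts(d, idx, Oinv, eta, f0, g, H);
    if (arma::norm(g) < tol) { conv = true; break; }
    bool accepted = false;
    for (int tr = 0; tr < 12; ++tr) {
      arma::vec step;
      bool ok = arma::solve(step, H + lambda * arma::eye(q, q), -g);
      if (ok) {
        arma::vec eta_try = eta + step;
        arma::vec f_try;
        double h_try = h_of(d, idx, Oinv, eta_try, &f_try);
        if (std::isfinite(h_try) && h_try <= h) {
          if (h - h_try < tol * (1.0 + std::abs(h)) && arma::norm(step) < tol) {
            eta = eta_try; h = h_try; f0 = f_try; conv = true;
          } else {
            eta = eta_try; h = h_try; f0 = f_try;
          }
          lambda = std::max(lambda * 0.3, 1e-8);
          accepted = true;
          break;
        }
      }
      lambda *= 10.0;
    }
    if (conv) break;
    if (!accepted) { conv = arma::norm(g) < 100 * tol; break; }
  }
  gn_parts(d, idx, Oinv, eta, f0, g, H);

  arma::mat Hld = H;                      // Hessian used for the log-det
  if (hess_method == 2) {                 // exact: FD of the GN gradient
    const double step = 1e-4;
    arma::mat Hfd(q, q);
    for (arma::uword j = 0; j < q; ++j) {
      arma::vec ep = eta, em = eta;
      ep(j) += step; em(j) -= step;
      arma::vec gp, gm, fp_, fm_; arma::mat Hp;
      fp_ = f0; fm_ = f0;
      double hp = h_of(d, idx, Oinv, ep, &fp_);
      (void) hp;
      gn_parts(d, idx, Oinv, ep, fp_, gp, Hp);
      double hm = h_of(d, idx, Oinv, em, &fm_);
      (void) hm;
      gn_parts(d, idx, Oinv, em, fm_, gm, Hp);
      // note: gn_parts gradient is exact given exact J; FD-J error ~1e-5
      Hfd.col(j) = (gp - gm) / (2.0 * step);
    }
    Hld = 0.5 * (Hfd + Hfd.t());
    if (!Hld.is_sympd()) Hld = H;         // fall back to GN if indefinite
  }
  double ld_H; arma::log_det(ld_H, sgn, Hld);
  if (sgn <= 0) { arma::log_det(ld_H, sgn, H); }

  int ndrop = 0;
  double c2 = cond_m2ll(d, f0, &ndrop);
  // -2 log Lmarg ~ cond_m2ll + eta'Oinv eta + log|Omega| + log|H|
  double m2ll = c2 + arma::as_scalar(eta.t() * Oinv * eta) + ld_O + ld_H;
  return List::create(_["m2ll"] = m2ll, _["eta"] = eta, _["converged"] = conv,
                      _["grad_norm"] = arma::norm(g), _["n_dropped"] = ndrop,
                      _["cond_m2ll"] = c2);
}
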