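// Compiled non-cyclic boosting loop.
//
// This mirrors the R reference implementation (boost_init / boost_iteration)
// exactly: per iteration the per-parameter scores are computed, every
// centered-covariate base-learner plus an intercept learner is fitted to each
// score column by least squares, the best learner per parameter (lowest RSS,
// intercept last on ties) is compared across parameters by the empirical risk
// after a tentative nu-scaled update, and the single best update is committed.
// An equality test in the test suite keeps the two paths in lockstep.

#include <Rcpp.h>
using namespace Rcpp;

static const double LOG_SQRT_2PI = 0.918938533204672742;

// margin codes: 0 = weibull (log/log links), 1 = lognormal (identity/log)
struct MarginRow {
  double F;     // CDF at y
  double logf;  // log density at y
  double d_lf_mu, d_lf_sig, d_F_mu, d_F_sig;  // predictor-scale derivatives
};

static inline void margin_eval(int code, double ly, double emu, double esig,
                               bool derivs, MarginRow &out) {
  double sigma = std::exp(esig);
  if (code == 0) {
    double w = sigma * (ly - emu);
    double z = std::exp(w);
    double S = std::exp(-z);
    out.F = -std::expm1(-z);
    out.logf = esig - emu + (sigma - 1.0) * (ly - emu) - z;
    if (derivs) {
      out.d_lf_mu = sigma * (z - 1.0);
      out.d_lf_sig = 1.0 + w * (1.0 - z);
      out.d_F_mu = -sigma * z * S;
      out.d_F_sig = z * w * S;
    }
  } else {
    double r = (ly - emu) / sigma;
    out.F = R::pnorm(r, 0.0, 1.0, 1, 0);
    out.logf = -ly - esig - 0.5 * r * r - LOG_SQRT_2PI;
    if (derivs) {
      double phi = std::exp(-0.5 * r * r) * 0.398942280401432678;
      out.d_lf_mu = r / sigma;
      out.d_lf_sig = r * r - 1.0;
      out.d_F_mu = -phi / sigma;
      out.d_F_sig = -phi * r;
    }
  }
}

static inline double clip01(double p) {
  if (p < 1e-12) return 1e-12;
  if (p > 1.0 - 1e-12) return 1.0 - 1e-12;
  return p;
}

// copula codes: 0 = clayton, 1 = gaussian, 2 = gumbel
static inline double theta_from_eta(int cop, double eta) {
  if (cop == 0) { double t = std::exp(eta); return t < 1e-10 ? 1e-10 : t; }
  if (cop == 1) {
    double r = std::tanh(eta);
    if (r > 1.0 - 1e-7) r = 1.0 - 1e-7;
    if (r < -(1.0 - 1e-7)) r = -(1.0 - 1e-7);
    return r;
  }
  double t = 1.0 + std::exp(eta);
  return t < 1.0 + 1e-10 ? 1.0 + 1e-10 : t;
}

static inline double dtheta_deta(int cop, double th) {
  if (cop == 0) return th;
  if (cop == 1) return (1.0 - th) * (1.0 + th);
  return th - 1.0;
}

static inline double log_expm1(double x) {
  return x > 30.0 ? x : std::log(std::expm1(x));
}

static inline double logsumexp2(double a, double b) {
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// h(v | u) = dC/du; qa, qb are the normal quantiles of (u, v) for gaussian
static double h_vgu(int cop, double u, double v, double th,
                    double qa, double qb) {
  if (cop == 1) {
    double s = std::sqrt((1.0 - th) * (1.0 + th));
    return R::pnorm((qb - th * qa) / s, 0.0, 1.0, 1, 0);
  }
  if (cop == 0) {
    double lu = std::log(u), lv = std::log(v);
    double x1 = -th * lu, x2 = -th * lv;
    double m = x1 > x2 ? x1 : x2;
    double la = m + std::log(std::exp(x1 - m) + std::exp(x2 - m) -
                             std::exp(-m));
    return std::exp((-th - 1.0) * lu + (-1.0 / th - 1.0) * la);
  }
  double lx = std::log(-std::log(u)), lyv = std::log(-std::log(v));
  double ls = logsumexp2(th * lx, th * lyv);
  return std::exp(-std::exp(ls / th) + (th - 1.0) * lx +
                  (1.0 / th - 1.0) * ls - std::log(u));
}

// derivatives of h(v|u) wrt u, v, theta (mirrors .h_vgu_derivs)
static void h_vgu_derivs(int cop, double u, double v, double th,
                         double qa, double qb,
                         double &du, double &dv, double &dth) {
  if (cop == 1) {
    double s2 = (1.0 - th) * (1.0 + th), s = std::sqrt(s2);
    double z = (qb - th * qa) / s;
    double phiz = std::exp(-0.5 * z * z) * 0.398942280401432678;
    double phia = std::exp(-0.5 * qa * qa) * 0.398942280401432678;
    double phib = std::exp(-0.5 * qb * qb) * 0.398942280401432678;
    du = -phiz * th / (s * phia);
    dv = phiz / (s * phib);
    dth = phiz * (th * qb - qa) / (s2 * s);
    return;
  }
  if (cop == 0) {
    double lu = std::log(u), lv = std::log(v);
    double x1 = -th * lu, x2 = -th * lv;
    double m = x1 > x2 ? x1 : x2;
    double la = m + std::log(std::exp(x1 - m) + std::exp(x2 - m) -
                             std::exp(-m));
    du = -(th + 1.0) * std::exp((-th - 2.0) * lu + (-1.0 / th - 2.0) * la +
                                log_expm1(x2));
    dv = (1.0 + th) * std::exp((-th - 1.0) * (lu + lv) +
                               (-1.0 / th - 2.0) * la);
    if (th < 1e-4) {
      double s1 = 1e-5, hi = th + s1, lo = th - s1 > th * 0.5 ? th - s1 : th * 0.5;
      dth = (h_vgu(0, u, v, hi, 0, 0) - h_vgu(0, u, v, lo, 0, 0)) / (hi - lo);
    } else {
      double h = std::exp((-th - 1.0) * lu + (-1.0 / th - 1.0) * la);
      dth = h * (-lu + la / (th * th) +
                 (1.0 / th + 1.0) *
                   (std::exp(x1 - la) * lu + std::exp(x2 - la) * lv));
    }
    return;
  }
  // gumbel
  double lx = std::log(-std::log(u)), lyv = std::log(-std::log(v));
  double ls = logsumexp2(th * lx, th * lyv);
  double lb = ls / th, B = std::exp(lb);
  double h = std::exp(-B + (th - 1.0) * lx + (1.0 / th - 1.0) * ls -
                      std::log(u));
  dv = std::exp(-B + (lx + lyv) * (th - 1.0) + (2.0 / th - 2.0) * ls -
                std::log(u) - std::log(v) +
                std::log1p((th - 1.0) * std::exp(-lb)));
  double bracket = std::exp((th - 1.0) * lx) +
    (th - 1.0) * std::exp((th - 2.0) * lx) -
    (th - 1.0) * std::exp((2.0 * th - 2.0) * lx - ls);
  du = h * h * std::exp(B) -
    std::exp(-B - 2.0 * std::log(u) + (1.0 / th - 1.0) * ls) * bracket;
  double step = 1e-5 * std::max(th - 1.0, 1.0);
  double hi = th + step;
  double lo = std::max(th - step, 1.0 + 0.5 * (th - 1.0));
  dth = (h_vgu(2, u, v, hi, 0, 0) - h_vgu(2, u, v, lo, 0, 0)) / (hi - lo);
}

struct CopCache {
  // per-row current state for the joint copula loss
  std::vector<double> eta;   // n x K column-major
  std::vector<double> u, v, qa, qb, theta;
  std::vector<MarginRow> mT, mC;
};

static void refresh_margin(int which, int mcode, int cop, const NumericVector &ly,
                           CopCache &c, int n, bool derivs) {
  const double *e_mu = &c.eta[(which == 0 ? 0 : 2) * n];
  const double *e_sig = &c.eta[(which == 0 ? 1 : 3) * n];
  for (int i = 0; i < n; ++i) {
    MarginRow &row = which == 0 ? c.mT[i] : c.mC[i];
    margin_eval(mcode, ly[i], e_mu[i], e_sig[i], derivs, row);
    double F = clip01(row.F);
    if (which == 0) {
      c.u[i] = F;
      if (cop == 1) c.qa[i] = R::qnorm(F, 0.0, 1.0, 1, 0);
    } else {
      c.v[i] = F;
      if (cop == 1) c.qb[i] = R::qnorm(F, 0.0, 1.0, 1, 0);
    }
  }
}

static double cop_risk(const CopCache &c, const IntegerVector &delta,
                       int cop, int n) {
  double risk = 0.0;
  for (int i = 0; i < n; ++i) {
    double h, lf;
    if (delta[i] == 1) {
      h = h_vgu(cop, c.u[i], c.v[i], c.theta[i], c.qa[i], c.qb[i]);
      lf = c.mT[i].logf;
    } else {
      h = h_vgu(cop, c.v[i], c.u[i], c.theta[i], c.qb[i], c.qa[i]);
      lf = c.mC[i].logf;
    }
    if (lf < -690.0) lf = -690.0;
    double om = 1.0 - h;
    if (om < 1e-12) om = 1e-12;
    risk -= lf + std::log(om);
  }
  return risk;
}

// risk after tentative update of column k (cache untouched)
static double cop_risk_update(const CopCache &c, const IntegerVector &delta,
                              const NumericVector &ly, int mT_code, int mC_code,
                              int cop, int n, int k, const double *upd) {
  double risk = 0.0;
  MarginRow row;
  for (int i = 0; i < n; ++i) {
    double u = c.u[i], v = c.v[i], th = c.theta[i];
    double qa = c.qa[i], qb = c.qb[i];
    double logfT = c.mT[i].logf, logfC = c.mC[i].logf;
    if (k <= 1) {
      double emu = c.eta[0 * n + i] + (k == 0 ? upd[i] : 0.0);
      double esig = c.eta[1 * n + i] + (k == 1 ? upd[i] : 0.0);
      margin_eval(mT_code, ly[i], emu, esig, false, row);
      u = clip01(row.F); logfT = row.logf;
      if (cop == 1) qa = R::qnorm(u, 0.0, 1.0, 1, 0);
    } else if (k <= 3) {
      double emu = c.eta[2 * n + i] + (k == 2 ? upd[i] : 0.0);
      double esig = c.eta[3 * n + i] + (k == 3 ? upd[i] : 0.0);
      margin_eval(mC_code, ly[i], emu, esig, false, row);
      v = clip01(row.F); logfC = row.logf;
      if (cop == 1) qb = R::qnorm(v, 0.0, 1.0, 1, 0);
    } else {
      th = theta_from_eta(cop, c.eta[4 * n + i] + upd[i]);
    }
    double h, lf;
    if (delta[i] == 1) {
      h = h_vgu(cop, u, v, th, qa, qb);
      lf = logfT;
    } else {
      h = h_vgu(cop, v, u, th, qb, qa);
      lf = logfC;
    }
    if (lf < -690.0) lf = -690.0;
    double om = 1.0 - h;
    if (om < 1e-12) om = 1e-12;
    risk -= lf + std::log(om);
  }
  return risk;
}

static void cop_apply(CopCache &c, const NumericVector &ly, int mT_code,
                      int mC_code, int cop, int n, int k, const double *upd) {
  double *col = &c.eta[k * n];
  for (int i = 0; i < n; ++i) col[i] += upd[i];
  if (k <= 1) refresh_margin(0, mT_code, cop, ly, c, n, true);
  else if (k <= 3) refresh_margin(1, mC_code, cop, ly, c, n, true);
  else for (int i = 0; i < n; ++i)
    c.theta[i] = theta_from_eta(cop, c.eta[4 * n + i]);
}

// scores d loglik / d eta -> n x 5 (mirrors .copula_scores_cache)
static void cop_scores(const CopCache &c, const IntegerVector &delta,
                       int cop, int n, double *G) {
  for (int i = 0; i < n; ++i) {
    double th = c.theta[i];
    double dth = dtheta_deta(cop, th);
    double du, dv, dthh, h;
    if (delta[i] == 1) {
      h = h_vgu(cop, c.u[i], c.v[i], th, c.qa[i], c.qb[i]);
      h_vgu_derivs(cop, c.u[i], c.v[i], th, c.qa[i], c.qb[i], du, dv, dthh);
      double om = 1.0 - h;
      double w = om > 1e-12 ? 1.0 : 0.0;
      if (om < 1e-12) om = 1e-12;
      const MarginRow &T = c.mT[i], &C = c.mC[i];
      G[0 * n + i] = T.d_lf_mu - w * du * T.d_F_mu / om;
      G[1 * n + i] = T.d_lf_sig - w * du * T.d_F_sig / om;
      G[2 * n + i] = -w * dv * C.d_F_mu / om;
      G[3 * n + i] = -w * dv * C.d_F_sig / om;
      G[4 * n + i] = -w * dthh * dth / om;
    } else {
      h = h_vgu(cop, c.v[i], c.u[i], th, c.qb[i], c.qa[i]);
      h_vgu_derivs(cop, c.v[i], c.u[i], th, c.qb[i], c.qa[i], du, dv, dthh);
      double om = 1.0 - h;
      double w = om > 1e-12 ? 1.0 : 0.0;
      if (om < 1e-12) om = 1e-12;
      const MarginRow &T = c.mT[i], &C = c.mC[i];
      G[0 * n + i] = -w * dv * T.d_F_mu / om;
      G[1 * n + i] = -w * dv * T.d_F_sig / om;
      G[2 * n + i] = C.d_lf_mu - w * du * C.d_F_mu / om;
      G[3 * n + i] = C.d_lf_sig - w * du * C.d_F_sig / om;
      G[4 * n + i] = -w * dthh * dth / om;
    }
  }
}

// ---- AFT (independence censoring) loss, 2 predictors ----------------------

struct AftCache { std::vector<double> eta; std::vector<MarginRow> m; };

static double aft_risk_rows(const AftCache &c, const IntegerVector &delta,
                            int n) {
  double risk = 0.0;
  for (int i = 0; i < n; ++i) {
    double lf = c.m[i].logf;
    if (lf < -690.0) lf = -690.0;
    double S = 1.0 - c.m[i].F;
    if (S < 1e-12) S = 1e-12;
    risk -= delta[i] == 1 ? lf : std::log(S);
  }
  return risk;
}

static double aft_risk_update(const AftCache &c, const IntegerVector &delta,
                              const NumericVector &ly, int mcode, int n,
                              int k, const double *upd) {
  double risk = 0.0;
  MarginRow row;
  for (int i = 0; i < n; ++i) {
    double emu = c.eta[0 * n + i] + (k == 0 ? upd[i] : 0.0);
    double esig = c.eta[1 * n + i] + (k == 1 ? upd[i] : 0.0);
    margin_eval(mcode, ly[i], emu, esig, false, row);
    double lf = row.logf;
    if (lf < -690.0) lf = -690.0;
    double S = 1.0 - row.F;
    if (S < 1e-12) S = 1e-12;
    risk -= delta[i] == 1 ? lf : std::log(S);
  }
  return risk;
}

static void aft_scores(const AftCache &c, const IntegerVector &delta, int n,
                       double *G) {
  for (int i = 0; i < n; ++i) {
    const MarginRow &m = c.m[i];
    double S = 1.0 - m.F;
    if (S < 1e-12) S = 1e-12;
    if (delta[i] == 1) {
      G[0 * n + i] = m.d_lf_mu;
      G[1 * n + i] = m.d_lf_sig;
    } else {
      G[0 * n + i] = -m.d_F_mu / S;
      G[1 * n + i] = -m.d_F_sig / S;
    }
  }
}

// ---- shared engine --------------------------------------------------------

// [[Rcpp::export(name = ".cpp_boost_engine")]]
List cpp_boost_engine(NumericVector y, IntegerVector delta, NumericMatrix Xc,
                      NumericVector ssx, NumericVector offsets, double nu,
                      int mstop, int mT_code, int mC_code, int cop_code,
                      bool is_aft,
                      Nullable<NumericVector> yv_, Nullable<IntegerVector> dv_,
                      Nullable<NumericMatrix> Xv_) {
  int n = y.size(), p = Xc.ncol();
  int K = is_aft ? 2 : 5;
  NumericVector ly(n);
  for (int i = 0; i < n; ++i) ly[i] = std::log(std::max(y[i], 1e-300));

  bool has_val = yv_.isNotNull();
  NumericVector yv; IntegerVector dv; NumericMatrix Xv;
  NumericVector lyv;
  int nv = 0;
  if (has_val) {
    yv = yv_.get(); dv = dv_.get(); Xv = Xv_.get();
    nv = yv.size();
    lyv = NumericVector(nv);
    for (int i = 0; i < nv; ++i) lyv[i] = std::log(std::max(yv[i], 1e-300));
  }

  // initialize caches at the offsets
  CopCache cc, ccv; AftCache ac, acv;
  if (is_aft) {
    ac.eta.assign((size_t)n * K, 0.0); ac.m.resize(n);
    for (int k = 0; k < K; ++k)
      for (int i = 0; i < n; ++i) ac.eta[k * n + i] = offsets[k];
    for (int i = 0; i < n; ++i)
      margin_eval(mT_code, ly[i], ac.eta[i], ac.eta[n + i], true, ac.m[i]);
    if (has_val) {
      acv.eta.assign((size_t)nv * K, 0.0); acv.m.resize(nv);
      for (int k = 0; k < K; ++k)
        for (int i = 0; i < nv; ++i) acv.eta[k * nv + i] = offsets[k];
      for (int i = 0; i < nv; ++i)
        margin_eval(mT_code, lyv[i], acv.eta[i], acv.eta[nv + i], true,
                    acv.m[i]);
    }
  } else {
    cc.eta.assign((size_t)n * K, 0.0);
    cc.u.resize(n); cc.v.resize(n); cc.qa.resize(n); cc.qb.resize(n);
    cc.theta.resize(n); cc.mT.resize(n); cc.mC.resize(n);
    for (int k = 0; k < K; ++k)
      for (int i = 0; i < n; ++i) cc.eta[k * n + i] = offsets[k];
    refresh_margin(0, mT_code, cop_code, ly, cc, n, true);
    refresh_margin(1, mC_code, cop_code, ly, cc, n, true);
    for (int i = 0; i < n; ++i)
      cc.theta[i] = theta_from_eta(cop_code, cc.eta[4 * n + i]);
    if (has_val) {
      ccv.eta.assign((size_t)nv * K, 0.0);
      ccv.u.resize(nv); ccv.v.resize(nv); ccv.qa.resize(nv); ccv.qb.resize(nv);
      ccv.theta.resize(nv); ccv.mT.resize(nv); ccv.mC.resize(nv);
      for (int k = 0; k < K; ++k)
        for (int i = 0; i < nv; ++i) ccv.eta[k * nv + i] = offsets[k];
      refresh_margin(0, mT_code, cop_code, lyv, ccv, nv, true);
      refresh_margin(1, mC_code, cop_code, lyv, ccv, nv, true);
      for (int i = 0; i < nv; ++i)
        ccv.theta[i] = theta_from_eta(cop_code, ccv.eta[4 * nv + i]);
    }
  }

  double risk0 = is_aft ? aft_risk_rows(ac, delta, n)
                        : cop_risk(cc, delta, cop_code, n);
  double risk0_val = NA_REAL;
  if (has_val)
    risk0_val = is_aft ? aft_risk_rows(acv, dv, nv)
                       : cop_risk(ccv, dv, cop_code, nv);

  IntegerVector trace_param(mstop), trace_learner(mstop);
  NumericVector trace_inc(mstop), risk_train(mstop), risk_val(mstop);
  std::vector<double> G((size_t)n * K), upd(n), updv;
  if (has_val) updv.resize(nv);

  for (int m = 0; m < mstop; ++m) {
    if (is_aft) aft_scores(ac, delta, n, G.data());
    else cop_scores(cc, delta, cop_code, n, G.data());

    double best_risk = R_PosInf;
    int best_k = -1, best_j = -1;
    double best_coef = 0.0;
    for (int k = 0; k < K; ++k) {
      const double *g = &G[(size_t)k * n];
      double gg = 0.0, gsum = 0.0;
      for (int i = 0; i < n; ++i) { gg += g[i] * g[i]; gsum += g[i]; }
      double gbar = gsum / n;
      // best base-learner for this parameter: lowest RSS; ties go to the
      // lowest covariate index, with the intercept learner last
      int j_sel = -1;
      double coef_sel = 0.0, rss_sel = R_PosInf;
      for (int j = 0; j < p; ++j) {
        if (ssx[j] <= 0.0) continue;
        double num = 0.0;
        const double *x = &Xc[0] + (size_t)j * n;
        for (int i = 0; i < n; ++i) num += g[i] * x[i];
        double b = num / ssx[j];
        double rss = gg - b * b * ssx[j];
        if (rss < rss_sel) { j_sel = j; coef_sel = b; rss_sel = rss; }
      }
      double rss_int = gg - n * gbar * gbar;
      if (rss_int < rss_sel) { j_sel = -1; coef_sel = gbar; rss_sel = rss_int; }
      // tentative nu-scaled update and outer-loss comparison
      if (j_sel >= 0) {
        const double *x = &Xc[0] + (size_t)j_sel * n;
        for (int i = 0; i < n; ++i) upd[i] = nu * coef_sel * x[i];
      } else {
        for (int i = 0; i < n; ++i) upd[i] = nu * coef_sel;
      }
      double r = is_aft
        ? aft_risk_update(ac, delta, ly, mT_code, n, k, upd.data())
        : cop_risk_update(cc, delta, ly, mT_code, mC_code, cop_code, n, k,
                          upd.data());
      if (r < best_risk) {
        best_risk = r; best_k = k; best_j = j_sel; best_coef = coef_sel;
      }
    }
    if (!R_finite(best_risk))
      stop("non-finite risk at boosting iteration %d", m + 1);

    // commit
    if (best_j >= 0) {
      const double *x = &Xc[0] + (size_t)best_j * n;
      for (int i = 0; i < n; ++i) upd[i] = nu * best_coef * x[i];
    } else {
      for (int i = 0; i < n; ++i) upd[i] = nu * best_coef;
    }
    if (is_aft) {
      double *col = &ac.eta[(size_t)best_k * n];
      for (int i = 0; i < n; ++i) col[i] += upd[i];
      for (int i = 0; i < n; ++i)
        margin_eval(mT_code, ly[i], ac.eta[i], ac.eta[n + i], true, ac.m[i]);
    } else {
      cop_apply(cc, ly, mT_code, mC_code, cop_code, n, best_k, upd.data());
    }
    trace_param[m] = best_k + 1;
    trace_learner[m] = best_j + 1;  // 0 = intercept
    trace_inc[m] = nu * best_coef;
    risk_train[m] = best_risk;

    if (has_val) {
      if (best_j >= 0) {
        const double *x = &Xv[0] + (size_t)best_j * nv;
        for (int i = 0; i < nv; ++i) updv[i] = nu * best_coef * x[i];
      } else {
        for (int i = 0; i < nv; ++i) updv[i] = nu * best_coef;
      }
      if (is_aft) {
        double *col = &acv.eta[(size_t)best_k * nv];
        for (int i = 0; i < nv; ++i) col[i] += updv[i];
        for (int i = 0; i < nv; ++i)
          margin_eval(mT_code, lyv[i], acv.eta[i], acv.eta[nv + i], true,
                      acv.m[i]);
        risk_val[m] = aft_risk_rows(acv, dv, nv);
      } else {
        cop_apply(ccv, lyv, mT_code, mC_code, cop_code, nv, best_k,
                  updv.data());
        risk_val[m] = cop_risk(ccv, dv, cop_code, nv);
      }
    }
    if (m % 256 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
    Named("trace_param") = trace_param,
    Named("trace_learner") = trace_learner,
    Named("trace_inc") = trace_inc,
    Named("risk_train") = risk_train,
    Named("risk0") = risk0);
  if (has_val) {
    out["risk_val"] = risk_val;
    out["risk0_val"] = risk0_val;
  }
  return out;
}
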