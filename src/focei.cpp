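// Laplace/FOCE-I likelihood kernel: per-subject damped Newton for the
// conditional modes and the Laplace-approximate -2 log marginal likelihood.
// Mirrors the reference R implementation (laplace_neg2ll) exactly; the R
// path remains in the package as the cross-checked reference.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Theta {
  double tv, tcl, tka, ev, ec, sigma, logdet2piom;
  double om_inv[3][3];
};

struct SubjData {
  double w, dose;
  const double *t, *y;
  int nobs;
};

static inline void conc_grad(double dose, double v, double cl, double ka,
                             double t, double &f, double &da, double &db,
                             double &dc) {
  double ke = cl / v;
  if (!std::isfinite(ke) || !std::isfinite(ka) || ke <= 0.0 || ka <= 0.0) {
    f = NAN; da = db = dc = 0.0;
    return;
  }
  double d = ka - ke, fke, fka;
  if (std::fabs(d) < 1e-6 * ke) {
    double E2 = std::exp(-ka * t);
    f = dose * ka * t * E2 / v;
    fke = -dose * ka * t * t * E2 / (2.0 * v);
    fka = f / ka + fke;
  } else {
    double A = dose * ka / (v * d);
    double E1 = std::exp(-ke * t), E2 = std::exp(-ka * t);
    f = A * (E1 - E2);
    fke = f / d - A * t * E1;
    fka = -f * ke / (ka * d) + A * t * E2;
  }
  da = -f - ke * fke;
  db = ke * fke;
  dc = ka * fka;
}

static inline void indiv_params(const Theta &th, const SubjData &sd,
                                const double eta[3], double &v, double &cl,
                                double &ka) {
  double wr = sd.w / 70.0;
  v = th.tv * std::exp(eta[0]) * std::pow(wr, th.ev);
  cl = th.tcl * std::exp(eta[1]) * std::pow(wr, th.ec);
  ka = th.tka * std::exp(eta[2]);
}

static double h_subj(const Theta &th, const SubjData &sd, const double eta[3]) {
  double v, cl, ka, f, da, db, dc;
  indiv_params(th, sd, eta, v, cl, ka);
  double acc = 0.0;
  for (int j = 0; j < sd.nobs; ++j) {
    conc_grad(sd.dose, v, cl, ka, sd.t[j], f, da, db, dc);
    if (!std::isfinite(f) || f <= 0.0) return R_PosInf;
    double r = sd.y[j] - f;
    double lg = th.sigma * f;
    acc += std::log(2.0 * M_PI) + 2.0 * std::log(lg) + r * r / (lg * lg);
  }
  double quad = 0.0;
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) quad += eta[a] * th.om_inv[a][b] * eta[b];
  return acc + quad + th.logdet2piom;
}

static void grad_subj(const Theta &th, const SubjData &sd, const double eta[3],
                      double g[3]) {
  double v, cl, ka, f, da, db, dc;
  indiv_params(th, sd, eta, v, cl, ka);
  double s2 = th.sigma * th.sigma;
  g[0] = g[1] = g[2] = 0.0;
  for (int j = 0; j < sd.nobs; ++j) {
    conc_grad(sd.dose, v, cl, ka, sd.t[j], f, da, db, dc);
    double r = sd.y[j] - f;
    double phi = 2.0 / f - 2.0 * r / (s2 * f * f) -
                 2.0 * r * r / (s2 * f * f * f);
    g[0] += phi * da;
    g[1] += phi * db;
    g[2] += phi * dc;
  }
  for (int a = 0; a < 3; ++a) {
    double p = 0.0;
    for (int b = 0; b < 3; ++b) p += th.om_inv[a][b] * eta[b];
    g[a] += 2.0 * p;
  }
}

static inline double det3(const double H[3][3]) {
  return H[0][0] * (H[1][1] * H[2][2] - H[1][2] * H[1][2]) -
         H[0][1] * (H[0][1] * H[2][2] - H[1][2] * H[0][2]) +
         H[0][2] * (H[0][1] * H[1][2] - H[1][1] * H[0][2]);
}

// in-place: clean non-finite entries, then ridge the diagonal until PD
static void ridge_pd(double H[3][3]) {
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b)
      if (!std::isfinite(H[a][b])) H[a][b] = 0.0;
  double base =
      1e-4 * (std::fabs(H[0][0]) + std::fabs(H[1][1]) + std::fabs(H[2][2])) / 3.0;
  double lam = 0.0;
  for (int pass = 0; pass < 60; ++pass) {
    double Hl[3][3];
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) Hl[a][b] = H[a][b];
    for (int a = 0; a < 3; ++a) Hl[a][a] += lam;
    double m1 = Hl[0][0];
    double m2 = Hl[0][0] * Hl[1][1] - Hl[0][1] * Hl[0][1];
    double m3 = det3(Hl);
    bool ok = std::isfinite(m1) && std::isfinite(m2) && std::isfinite(m3) &&
              m1 > 0.0 && m2 > 0.0 && m3 > 0.0;
    if (ok) {
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b) H[a][b] = Hl[a][b];
      return;
    }
    lam = std::max(lam * 10.0, std::max(base, 1e-8));
  }
  for (int a = 0; a < 3; ++a) H[a][a] += lam;
}

static void solve3(const double H[3][3], const double g[3], double x[3]) {
  double det = det3(H);
  double i00 = (H[1][1] * H[2][2] - H[1][2] * H[1][2]) / det;
  double i01 = (H[0][2] * H[1][2] - H[0][1] * H[2][2]) / det;
  double i02 = (H[0][1] * H[1][2] - H[0][2] * H[1][1]) / det;
  double i11 = (H[0][0] * H[2][2] - H[0][2] * H[0][2]) / det;
  double i12 = (H[0][2] * H[0][1] - H[0][0] * H[1][2]) / det;
  double i22 = (H[0][0] * H[1][1] - H[0][1] * H[0][1]) / det;
  x[0] = i00 * g[0] + i01 * g[1] + i02 * g[2];
  x[1] = i01 * g[0] + i11 * g[1] + i12 * g[2];
  x[2] = i02 * g[0] + i12 * g[1] + i22 * g[2];
}

// forward-FD Hessian of h from the analytic gradient, symmetrized
static void hess_forward(const Theta &th, const SubjData &sd,
                         const double eta[3], const double g0[3],
                         double H[3][3]) {
  const double del = 1e-4;
  double cols[3][3];
  for (int k = 0; k < 3; ++k) {
    double ep[3] = {eta[0], eta[1], eta[2]};
    ep[k] += del;
    double gk[3];
    grad_subj(th, sd, ep, gk);
    for (int a = 0; a < 3; ++a) cols[k][a] = (gk[a] - g0[a]) / del;
  }
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) H[a][b] = (cols[a][b] + cols[b][a]) / 2.0;
}

// central-FD Hessian (used for the Laplace log-determinant)
static void hess_central(const Theta &th, const SubjData &sd,
                         const double eta[3], double H[3][3]) {
  const double del = 1e-4;
  double cols[3][3];
  for (int k = 0; k < 3; ++k) {
    double ep[3] = {eta[0], eta[1], eta[2]};
    double em[3] = {eta[0], eta[1], eta[2]};
    ep[k] += del;
    em[k] -= del;
    double gp[3], gm[3];
    grad_subj(th, sd, ep, gp);
    grad_subj(th, sd, em, gm);
    for (int a = 0; a < 3; ++a) cols[k][a] = (gp[a] - gm[a]) / (2.0 * del);
  }
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) H[a][b] = (cols[a][b] + cols[b][a]) / 2.0;
}

// damped Newton for one subject's conditional mode
static bool newton_subj(const Theta &th, const SubjData &sd, double eta[3],
                        double &h, double gtol, int maxit) {
  h = h_subj(th, sd, eta);
  if (!std::isfinite(h)) {
    eta[0] = eta[1] = eta[2] = 0.0;
    h = h_subj(th, sd, eta);
    if (!std::isfinite(h)) return false;
  }
  for (int it = 0; it < maxit; ++it) {
    double g[3];
    grad_subj(th, sd, eta, g);
    for (int a = 0; a < 3; ++a)
      if (!std::isfinite(g[a])) g[a] = 1.0;
    double gmax = std::max(std::fabs(g[0]),
                           std::max(std::fabs(g[1]), std::fabs(g[2])));
    if (gmax <= gtol) break;
    double H[3][3];
    hess_forward(th, sd, eta, g, H);
    ridge_pd(H);
    double step[3];
    solve3(H, g, step);
    for (int a = 0; a < 3; ++a)
      if (!std::isfinite(step[a])) step[a] = 0.0;
    double alpha = 1.0;
    bool accepted = false;
    for (int ls = 0; ls < 12; ++ls) {
      double trial[3] = {eta[0] - alpha * step[0], eta[1] - alpha * step[1],
                         eta[2] - alpha * step[2]};
      double ht = h_subj(th, sd, trial);
      if (std::isfinite(ht) && ht < h) {
        for (int a = 0; a < 3; ++a) eta[a] = trial[a];
        h = ht;
        accepted = true;
        break;
      }
      alpha /= 2.0;
    }
    if (!accepted) break;
  }
  return std::isfinite(h);
}

// [[Rcpp::export(name = ".laplace_neg2ll_cpp")]]
List laplace_neg2ll_cpp(double tv, double tcl, double tka, double ev, double ec,
                        NumericMatrix om_inv, double logdet2piom, double sigma,
                        NumericVector w, NumericVector dose,
                        IntegerVector obs_start, IntegerVector obs_len,
                        NumericVector ot, NumericVector oy,
                        NumericMatrix eta0, double gtol, int maxit) {
  int n = w.size();
  Theta th;
  th.tv = tv; th.tcl = tcl; th.tka = tka; th.ev = ev; th.ec = ec;
  th.sigma = sigma; th.logdet2piom = logdet2piom;
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) th.om_inv[a][b] = om_inv(a, b);
  NumericMatrix eta(n, 3);
  double value = 0.0;
  bool ok = true;
  for (int i = 0; i < n && ok; ++i) {
    SubjData sd;
    sd.w = w[i];
    sd.dose = dose[i];
    sd.t = &ot[obs_start[i]];
    sd.y = &oy[obs_start[i]];
    sd.nobs = obs_len[i];
    double e[3] = {eta0(i, 0), eta0(i, 1), eta0(i, 2)};
    double h;
    if (!newton_subj(th, sd, e, h, gtol, maxit)) {
      ok = false;
      break;
    }
    double H[3][3];
    hess_central(th, sd, e, H);
    ridge_pd(H);
    double d = det3(H);
    if (!(d > 0.0) || !std::isfinite(d)) {
      ok = false;
      break;
    }
    value += h + std::log(d) - 3.0 * (std::log(2.0) + std::log(2.0 * M_PI));
    for (int a = 0; a < 3; ++a) eta(i, a) = e[a];
  }
  if (!ok || !std::isfinite(value)) value = R_PosInf;
  return List::create(_["value"] = value, _["eta"] = eta);
}
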