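// Marginalized joint log posterior of the shared-parameter joint latent
// class model, its analytic gradient, and a compiled No-U-Turn sampler
// driving it. Parameters live in the unconstrained sampling space
// (log variances / log Weibull shape; random effects either centered (b)
// or non-centered (u, b = sqrt(Sigma) * u)).
//
// The model data list `md` is prepared on the R side (prepare_model_data):
// all design matrices, including those evaluated at the per-subject
// Gauss-Legendre quadrature nodes on (0, T_i), are precomputed so that the
// density is a flat pass over subjects.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

struct Dims {
  int n, G, r, p, q, pW, nq, assoc; // assoc: 0 none, 1 value, 2 slope
  bool noncentered, use_ig;
  int per_class;   // theta length per class
  int n_theta;     // total continuous structural parameters
  int n_par;       // n_theta + n*G*r random-effect coordinates
};

static Dims get_dims(const List& md) {
  Dims d;
  d.n  = as<int>(md["n"]);  d.G  = as<int>(md["G"]);
  d.r  = as<int>(md["r"]);  d.p  = as<int>(md["p"]);
  d.q  = as<int>(md["q"]);  d.pW = as<int>(md["pW"]);
  d.nq = as<int>(md["nq"]); d.assoc = as<int>(md["assoc"]);
  d.noncentered = as<bool>(md["noncentered"]);
  d.use_ig = as<bool>(md["use_ig"]);
  int a = (d.assoc != 0) ? 1 : 0;
  d.per_class = d.p + 1 + d.r + 2 + d.q + a;
  d.n_theta = d.G * d.per_class + (d.G - 1) * (1 + d.pW);
  d.n_par = d.n_theta + d.n * d.G * d.r;
  return d;
}

// offsets: class block [beta(p) | log sigma2 | log Sigma(r) | log phi0 |
//                       phi1 | gamma(q) | alpha?], then psi blocks, then
//                       random effects subject-major.
static inline int cls_off(const Dims& d, int g) { return g * d.per_class; }
static inline int off_lsig(const Dims& d)  { return d.p; }
static inline int off_lSig(const Dims& d)  { return d.p + 1; }
static inline int off_lphi0(const Dims& d) { return d.p + 1 + d.r; }
static inline int off_phi1(const Dims& d)  { return d.p + 2 + d.r; }
static inline int off_gam(const Dims& d)   { return d.p + 3 + d.r; }
static inline int off_alpha(const Dims& d) { return d.p + 3 + d.r + d.q; }
static inline int psi_off(const Dims& d, int g) {
  return d.G * d.per_class + g * (1 + d.pW);
}
static inline int re_off(const Dims& d, int i, int g) {
  return d.n_theta + (i * d.G + g) * d.r;
}

// model data parsed to raw column-major pointers (kept alive by the
// NumericMatrix/Vector handles inside)
struct MD {
  Dims d;
  NumericVector y, Tobs, logT, logsq, wq;
  IntegerVector sub_start, sub_len, delta;
  NumericMatrix X, Z, Wt, XT, ZT, Xq, Zq, W, XTa, ZTa, Xqa, Zqa;
  double s_beta, s_surv, s_psi, a_phi, b_phi, s_sig, alpha_b, lambda,
      ig_a, ig_b;
  const double *py, *plogT, *plogsq, *pwq;
  const int *pstart, *plen, *pdelta;
  const double *pX, *pZ, *pWt, *pXT, *pZT, *pXq, *pZq, *pW, *pXTa, *pZTa,
      *pXqa, *pZqa;
  int N;  // longitudinal rows
};

static MD parse_md(const List& md) {
  MD m;
  m.d = get_dims(md);
  m.y = md["y"]; m.Tobs = md["Tobs"]; m.logT = md["logT"];
  m.logsq = md["logsq"]; m.wq = md["wq"];
  m.sub_start = md["sub_start"]; m.sub_len = md["sub_len"];
  m.delta = md["delta"];
  m.X = as<NumericMatrix>(md["X"]); m.Z = as<NumericMatrix>(md["Z"]);
  m.Wt = as<NumericMatrix>(md["Wt"]);
  m.XT = as<NumericMatrix>(md["XT"]); m.ZT = as<NumericMatrix>(md["ZT"]);
  m.Xq = as<NumericMatrix>(md["Xq"]); m.Zq = as<NumericMatrix>(md["Zq"]);
  m.W = as<NumericMatrix>(md["W"]);
  if (m.d.assoc == 2) {
    m.XTa = as<NumericMatrix>(md["XTs"]); m.ZTa = as<NumericMatrix>(md["ZTs"]);
    m.Xqa = as<NumericMatrix>(md["Xqs"]); m.Zqa = as<NumericMatrix>(md["Zqs"]);
  } else {
    m.XTa = m.XT; m.ZTa = m.ZT; m.Xqa = m.Xq; m.Zqa = m.Zq;
  }
  m.s_beta = as<double>(md["scale_beta"]);
  m.s_surv = as<double>(md["scale_surv"]);
  m.s_psi  = as<double>(md["scale_psi"]);
  m.a_phi  = as<double>(md["shape_phi"]);
  m.b_phi  = as<double>(md["rate_phi"]);
  m.s_sig  = as<double>(md["scale_sigma2"]);
  m.alpha_b = as<double>(md["alpha_b"]);
  m.lambda  = as<double>(md["lambda"]);
  m.ig_a = as<double>(md["ig_shape"]);
  m.ig_b = as<double>(md["ig_scale"]);
  m.py = m.y.begin(); m.plogT = m.logT.begin();
  m.plogsq = m.logsq.begin(); m.pwq = m.wq.begin();
  m.pstart = m.sub_start.begin(); m.plen = m.sub_len.begin();
  m.pdelta = m.delta.begin();
  m.pX = m.X.begin(); m.pZ = m.Z.begin(); m.pWt = m.Wt.begin();
  m.pXT = m.XT.begin(); m.pZT = m.ZT.begin();
  m.pXq = m.Xq.begin(); m.pZq = m.Zq.begin();
  m.pW = m.W.begin();
  m.pXTa = m.XTa.begin(); m.pZTa = m.ZTa.begin();
  m.pXqa = m.Xqa.begin(); m.pZqa = m.Zqa.begin();
  m.N = m.X.nrow();
  return m;
}

// column-major element access helpers
static inline double at(const double* M, int nrow, int i, int j) {
  return M[j * nrow + i];
}

struct Work {
  std::vector<double> beta, Sig, sSig, gam;   // G * (p | r | r | q)
  std::vector<double> sigma2, lsig, phi0, lphi0, phi1, alpha;
  std::vector<double> lw, eta, wg, gb, b, Hk, bsave, Hsv, muTsv;
  void init(const Dims& d) {
    beta.assign(d.G * d.p, 0.0); Sig.assign(d.G * d.r, 0.0);
    sSig.assign(d.G * d.r, 0.0); gam.assign(d.G * std::max(d.q, 1), 0.0);
    sigma2.assign(d.G, 0.0); lsig.assign(d.G, 0.0); phi0.assign(d.G, 0.0);
    lphi0.assign(d.G, 0.0); phi1.assign(d.G, 0.0); alpha.assign(d.G, 0.0);
    lw.assign(d.G, 0.0); eta.assign(d.G, 0.0); wg.assign(d.G, 0.0);
    gb.assign(d.r, 0.0); b.assign(d.r, 0.0);
    Hk.assign(d.G * d.nq, 0.0); bsave.assign(d.G * d.r, 0.0);
    Hsv.assign(d.G, 0.0); muTsv.assign(d.G, 0.0);
  }
};

// Core evaluation. Returns the sampling-space log posterior; fills `grad`
// (length n_par) when non-null; stores the natural-scale log joint (log
// transform Jacobians removed, non-centered u mapped to b) in *lp_joint
// when non-null. Returns -inf (no error) for non-finite results.
static double lp_grad_core(const double* par, const MD& m, Work& w,
                           double* grad, double* lp_joint) {
  const Dims& d = m.d;
  bool gw = grad != nullptr;
  if (gw) std::fill(grad, grad + d.n_par, 0.0);

  for (int g = 0; g < d.G; ++g) {
    int o = cls_off(d, g);
    for (int j = 0; j < d.p; ++j) w.beta[g * d.p + j] = par[o + j];
    w.lsig[g] = par[o + off_lsig(d)];
    w.sigma2[g] = std::exp(w.lsig[g]);
    for (int k = 0; k < d.r; ++k) {
      w.Sig[g * d.r + k] = std::exp(par[o + off_lSig(d) + k]);
      w.sSig[g * d.r + k] = std::sqrt(w.Sig[g * d.r + k]);
    }
    w.lphi0[g] = par[o + off_lphi0(d)];
    w.phi0[g] = std::exp(w.lphi0[g]);
    w.phi1[g] = par[o + off_phi1(d)];
    for (int j = 0; j < d.q; ++j) w.gam[g * d.q + j] = par[o + off_gam(d) + j];
    w.alpha[g] = (d.assoc != 0) ? par[o + off_alpha(d)] : 0.0;
  }

  double lp = 0.0, log_jac = 0.0;
  // log prior p(Theta) + Jacobians
  for (int g = 0; g < d.G; ++g) {
    int o = cls_off(d, g);
    for (int j = 0; j < d.p; ++j) {
      double bgj = w.beta[g * d.p + j];
      lp += -0.5 * LOG2PI - std::log(m.s_beta)
          - 0.5 * bgj * bgj / (m.s_beta * m.s_beta);
      if (gw) grad[o + j] += -bgj / (m.s_beta * m.s_beta);
    }
    lp += std::log(2.0) - std::log(m.s_sig) - 0.5 * LOG2PI
        - 0.5 * w.sigma2[g] * w.sigma2[g] / (m.s_sig * m.s_sig) + w.lsig[g];
    log_jac += w.lsig[g];
    if (gw) grad[o + off_lsig(d)] +=
        1.0 - w.sigma2[g] * w.sigma2[g] / (m.s_sig * m.s_sig);
    if (d.use_ig) {
      for (int k = 0; k < d.r; ++k) {
        double v = par[o + off_lSig(d) + k];
        lp += m.ig_a * std::log(m.ig_b) - lgamma(m.ig_a) - m.ig_a * v
            - m.ig_b * std::exp(-v);
        log_jac += v;
        if (gw) grad[o + off_lSig(d) + k] += -m.ig_a + m.ig_b * std::exp(-v);
      }
    } else {
      double S = 0.0;
      for (int k = 0; k < d.r; ++k) S += w.Sig[g * d.r + k];
      for (int k = 0; k < d.r; ++k) {
        double v = par[o + off_lSig(d) + k];
        lp += m.alpha_b * std::log(m.alpha_b) - lgamma(m.alpha_b)
            + m.alpha_b * v - m.alpha_b * w.Sig[g * d.r + k];
        log_jac += v;
        if (gw) grad[o + off_lSig(d) + k] +=
            m.alpha_b * (1.0 - w.Sig[g * d.r + k]);
      }
      lp += -m.lambda / std::sqrt(S);
      if (gw) {
        double c = 0.5 * m.lambda * std::pow(S, -1.5);
        for (int k = 0; k < d.r; ++k)
          grad[o + off_lSig(d) + k] += c * w.Sig[g * d.r + k];
      }
    }
    lp += m.a_phi * std::log(m.b_phi) - lgamma(m.a_phi)
        + m.a_phi * w.lphi0[g] - m.b_phi * w.phi0[g];
    log_jac += w.lphi0[g];
    if (gw) grad[o + off_lphi0(d)] += m.a_phi - m.b_phi * w.phi0[g];
    lp += -0.5 * LOG2PI - std::log(m.s_surv)
        - 0.5 * w.phi1[g] * w.phi1[g] / (m.s_surv * m.s_surv);
    if (gw) grad[o + off_phi1(d)] += -w.phi1[g] / (m.s_surv * m.s_surv);
    for (int j = 0; j < d.q; ++j) {
      double gg = w.gam[g * d.q + j];
      lp += -0.5 * LOG2PI - std::log(m.s_surv)
          - 0.5 * gg * gg / (m.s_surv * m.s_surv);
      if (gw) grad[o + off_gam(d) + j] += -gg / (m.s_surv * m.s_surv);
    }
    if (d.assoc != 0) {
      lp += -0.5 * LOG2PI - std::log(m.s_surv)
          - 0.5 * w.alpha[g] * w.alpha[g] / (m.s_surv * m.s_surv);
      if (gw) grad[o + off_alpha(d)] += -w.alpha[g] / (m.s_surv * m.s_surv);
    }
  }
  for (int g = 0; g < d.G - 1; ++g) {
    int o = psi_off(d, g);
    for (int j = 0; j < 1 + d.pW; ++j) {
      double v = par[o + j];
      lp += -0.5 * LOG2PI - std::log(m.s_psi)
          - 0.5 * v * v / (m.s_psi * m.s_psi);
      if (gw) grad[o + j] += -v / (m.s_psi * m.s_psi);
    }
  }

  // subjects
  for (int i = 0; i < d.n; ++i) {
    // membership log-probabilities
    double emax = 0.0;  // eta_G = 0
    for (int g = 0; g < d.G; ++g) {
      if (g < d.G - 1) {
        int o = psi_off(d, g);
        double e = par[o];
        for (int j = 0; j < d.pW; ++j) e += at(m.pW, d.n, i, j) * par[o + 1 + j];
        w.eta[g] = e;
        if (e > emax) emax = e;
      } else w.eta[g] = 0.0;
    }
    double esum = 0.0;
    for (int g = 0; g < d.G; ++g) esum += std::exp(w.eta[g] - emax);
    double le = emax + std::log(esum);

    int st = m.pstart[i], ni = m.plen[i];
    int del = m.pdelta[i];

    for (int g = 0; g < d.G; ++g) {
      int ro = re_off(d, i, g);
      for (int k = 0; k < d.r; ++k) {
        double raw = par[ro + k];
        w.bsave[g * d.r + k] = d.noncentered ? w.sSig[g * d.r + k] * raw : raw;
      }
      const double* bg = &w.bsave[g * d.r];
      const double* betag = &w.beta[g * d.p];
      double ll = 0.0;
      for (int j = 0; j < ni; ++j) {
        int row = st + j;
        double mu = 0.0;
        for (int c = 0; c < d.p; ++c) mu += at(m.pX, m.N, row, c) * betag[c];
        for (int c = 0; c < d.r; ++c) mu += at(m.pZ, m.N, row, c) * bg[c];
        double res = m.py[row] - mu;
        ll += -0.5 * LOG2PI - 0.5 * w.lsig[g] - 0.5 * res * res / w.sigma2[g];
      }
      double wg_lin = 0.0;
      for (int c = 0; c < d.q; ++c) wg_lin += at(m.pWt, d.n, i, c) * w.gam[g * d.q + c];
      double H = 0.0;
      int nqn = d.n * d.nq;
      for (int k = 0; k < d.nq; ++k) {
        int row = i * d.nq + k;
        double wqk = m.pwq[row];
        if (wqk == 0.0) { w.Hk[g * d.nq + k] = 0.0; continue; }
        double mua = 0.0;
        if (d.assoc != 0) {
          for (int c = 0; c < d.p; ++c) mua += at(m.pXqa, nqn, row, c) * betag[c];
          for (int c = 0; c < d.r; ++c) mua += at(m.pZqa, nqn, row, c) * bg[c];
        }
        double lh = w.lphi0[g] + (w.phi0[g] - 1.0) * m.plogsq[row] + w.phi1[g]
                  + wg_lin + w.alpha[g] * mua;
        double Hkv = wqk * std::exp(lh);
        w.Hk[g * d.nq + k] = Hkv;
        H += Hkv;
      }
      w.Hsv[g] = H;
      double lsurv = -H;
      double muTa = 0.0;
      if (del == 1) {
        if (d.assoc != 0) {
          for (int c = 0; c < d.p; ++c) muTa += at(m.pXTa, d.n, i, c) * betag[c];
          for (int c = 0; c < d.r; ++c) muTa += at(m.pZTa, d.n, i, c) * bg[c];
        }
        lsurv += w.lphi0[g] + (w.phi0[g] - 1.0) * m.plogT[i] + w.phi1[g]
               + wg_lin + w.alpha[g] * muTa;
      }
      w.muTsv[g] = muTa;
      w.lw[g] = (w.eta[g] - le) + ll + lsurv;
    }
    double lmax = w.lw[0];
    for (int g = 1; g < d.G; ++g) if (w.lw[g] > lmax) lmax = w.lw[g];
    if (!R_FINITE(lmax)) return R_NegInf;
    double lsum = 0.0;
    for (int g = 0; g < d.G; ++g) lsum += std::exp(w.lw[g] - lmax);
    double li = lmax + std::log(lsum);
    lp += li;

    // random-effect prior term, all classes
    for (int g = 0; g < d.G; ++g) {
      int ro = re_off(d, i, g);
      for (int k = 0; k < d.r; ++k) {
        double raw = par[ro + k];
        if (d.noncentered) lp += -0.5 * LOG2PI - 0.5 * raw * raw;
        else lp += -0.5 * LOG2PI - std::log(w.sSig[g * d.r + k])
                 - 0.5 * raw * raw / w.Sig[g * d.r + k];
      }
    }

    if (!gw) continue;

    for (int g = 0; g < d.G; ++g) w.wg[g] = std::exp(w.lw[g] - li);

    for (int g = 0; g < d.G; ++g) {
      double wgt = w.wg[g];
      int o = cls_off(d, g);
      int ro = re_off(d, i, g);
      const double* bg = &w.bsave[g * d.r];
      const double* betag = &w.beta[g * d.p];
      for (int k = 0; k < d.r; ++k) w.gb[k] = 0.0;

      double dlsig_acc = 0.0;
      for (int j = 0; j < ni; ++j) {
        int row = st + j;
        double mu = 0.0;
        for (int c = 0; c < d.p; ++c) mu += at(m.pX, m.N, row, c) * betag[c];
        for (int c = 0; c < d.r; ++c) mu += at(m.pZ, m.N, row, c) * bg[c];
        double res = m.py[row] - mu;
        double rs = res / w.sigma2[g];
        for (int c = 0; c < d.p; ++c) grad[o + c] += wgt * rs * at(m.pX, m.N, row, c);
        for (int c = 0; c < d.r; ++c) w.gb[c] += rs * at(m.pZ, m.N, row, c);
        dlsig_acc += -0.5 + 0.5 * res * res / w.sigma2[g];
      }
      grad[o + off_lsig(d)] += wgt * dlsig_acc;

      double H = w.Hsv[g];
      double dphi1 = (double)del - H;
      grad[o + off_phi1(d)] += wgt * dphi1;
      for (int c = 0; c < d.q; ++c)
        grad[o + off_gam(d) + c] += wgt * dphi1 * at(m.pWt, d.n, i, c);
      double dlphi0 = (del == 1) ? (1.0 + w.phi0[g] * m.plogT[i]) : 0.0;
      int nqn = d.n * d.nq;
      for (int k = 0; k < d.nq; ++k) {
        double Hkv = w.Hk[g * d.nq + k];
        if (Hkv == 0.0) continue;
        dlphi0 -= Hkv * (1.0 + w.phi0[g] * m.plogsq[i * d.nq + k]);
      }
      grad[o + off_lphi0(d)] += wgt * dlphi0;
      if (d.assoc != 0) {
        double dalpha = (del == 1) ? w.muTsv[g] : 0.0;
        for (int k = 0; k < d.nq; ++k) {
          int row = i * d.nq + k;
          double Hkv = w.Hk[g * d.nq + k];
          if (Hkv == 0.0) continue;
          double mua = 0.0;
          for (int c = 0; c < d.p; ++c) mua += at(m.pXqa, nqn, row, c) * betag[c];
          for (int c = 0; c < d.r; ++c) mua += at(m.pZqa, nqn, row, c) * bg[c];
          dalpha -= Hkv * mua;
          double cf = wgt * w.alpha[g] * Hkv;
          for (int c = 0; c < d.p; ++c) grad[o + c] -= cf * at(m.pXqa, nqn, row, c);
          for (int c = 0; c < d.r; ++c) w.gb[c] -= w.alpha[g] * Hkv * at(m.pZqa, nqn, row, c);
        }
        if (del == 1) {
          for (int c = 0; c < d.p; ++c)
            grad[o + c] += wgt * w.alpha[g] * at(m.pXTa, d.n, i, c);
          for (int c = 0; c < d.r; ++c)
            w.gb[c] += w.alpha[g] * at(m.pZTa, d.n, i, c);
        }
        grad[o + off_alpha(d)] += wgt * dalpha;
      }

      for (int k = 0; k < d.r; ++k) {
        double raw = par[ro + k];
        if (d.noncentered) {
          grad[ro + k] += wgt * w.gb[k] * w.sSig[g * d.r + k] - raw;
          grad[o + off_lSig(d) + k] += wgt * 0.5 * w.gb[k] * bg[k];
        } else {
          grad[ro + k] += wgt * w.gb[k] - raw / w.Sig[g * d.r + k];
          grad[o + off_lSig(d) + k] += -0.5 + 0.5 * raw * raw / w.Sig[g * d.r + k];
        }
      }
    }

    if (d.G > 1) {
      for (int g = 0; g < d.G - 1; ++g) {
        double pis = std::exp(w.eta[g] - le);
        double diff = w.wg[g] - pis;
        int o = psi_off(d, g);
        grad[o] += diff;
        for (int j = 0; j < d.pW; ++j) grad[o + 1 + j] += diff * at(m.pW, d.n, i, j);
      }
    }
  }

  if (lp_joint != nullptr) {
    double lj = lp - log_jac;
    if (d.noncentered) {
      double sls = 0.0;
      for (int g = 0; g < d.G; ++g)
        for (int k = 0; k < d.r; ++k) sls += std::log(w.sSig[g * d.r + k]);
      lj -= d.n * sls;
    }
    *lp_joint = lj;
  }
  if (!R_FINITE(lp)) return R_NegInf;
  return lp;
}

// [[Rcpp::export]]
IntegerVector jlcm_par_sizes_cpp(List md) {
  Dims d = get_dims(md);
  return IntegerVector::create(_["n_theta"] = d.n_theta, _["n_par"] = d.n_par,
                               _["per_class"] = d.per_class);
}

// [[Rcpp::export]]
List jlcm_lp_grad_cpp(NumericVector par, List md, bool grad_wanted = true) {
  MD m = parse_md(md);
  if ((int)par.size() != m.d.n_par)
    stop("parameter vector has length %d, expected %d", (int)par.size(),
         m.d.n_par);
  Work w; w.init(m.d);
  double lp_joint = NA_REAL;
  if (grad_wanted) {
    NumericVector grad(m.d.n_par);
    double lp = lp_grad_core(par.begin(), m, w, grad.begin(), &lp_joint);
    return List::create(_["lp"] = lp, _["lp_joint"] = lp_joint,
                        _["grad"] = grad);
  }
  double lp = lp_grad_core(par.begin(), m, w, nullptr, &lp_joint);
  return List::create(_["lp"] = lp, _["lp_joint"] = lp_joint);
}

// Per-subject, per-class complete-data log weights
// log pi_ig + log p(y_i | b_ig, g) + log p(T_i, Delta_i | b_ig, g).
// Rows = subjects, cols = classes; used by the exact class-indicator
// sampler and the pointwise likelihood matrix.
// [[Rcpp::export]]
NumericMatrix jlcm_class_logweights_cpp(NumericVector par, List md) {
  MD m = parse_md(md);
  const Dims& d = m.d;
  if ((int)par.size() != d.n_par)
    stop("parameter vector has length %d, expected %d", (int)par.size(),
         d.n_par);
  Work w; w.init(d);
  const double* p = par.begin();
  for (int g = 0; g < d.G; ++g) {
    int o = cls_off(d, g);
    for (int j = 0; j < d.p; ++j) w.beta[g * d.p + j] = p[o + j];
    w.lsig[g] = p[o + off_lsig(d)];
    w.sigma2[g] = std::exp(w.lsig[g]);
    for (int k = 0; k < d.r; ++k) {
      w.Sig[g * d.r + k] = std::exp(p[o + off_lSig(d) + k]);
      w.sSig[g * d.r + k] = std::sqrt(w.Sig[g * d.r + k]);
    }
    w.lphi0[g] = p[o + off_lphi0(d)];
    w.phi0[g] = std::exp(w.lphi0[g]);
    w.phi1[g] = p[o + off_phi1(d)];
    for (int j = 0; j < d.q; ++j) w.gam[g * d.q + j] = p[o + off_gam(d) + j];
    w.alpha[g] = (d.assoc != 0) ? p[o + off_alpha(d)] : 0.0;
  }
  NumericMatrix out(d.n, d.G);
  int nqn = d.n * d.nq;
  for (int i = 0; i < d.n; ++i) {
    double emax = 0.0;
    for (int g = 0; g < d.G; ++g) {
      if (g < d.G - 1) {
        int o = psi_off(d, g);
        double e = p[o];
        for (int j = 0; j < d.pW; ++j) e += at(m.pW, d.n, i, j) * p[o + 1 + j];
        w.eta[g] = e;
        if (e > emax) emax = e;
      } else w.eta[g] = 0.0;
    }
    double esum = 0.0;
    for (int g = 0; g < d.G; ++g) esum += std::exp(w.eta[g] - emax);
    double le = emax + std::log(esum);
    int st = m.pstart[i], ni = m.plen[i];
    for (int g = 0; g < d.G; ++g) {
      int ro = re_off(d, i, g);
      for (int k = 0; k < d.r; ++k) {
        double raw = p[ro + k];
        w.b[k] = d.noncentered ? w.sSig[g * d.r + k] * raw : raw;
      }
      const double* betag = &w.beta[g * d.p];
      double ll = w.eta[g] - le;
      for (int j = 0; j < ni; ++j) {
        int row = st + j;
        double mu = 0.0;
        for (int c = 0; c < d.p; ++c) mu += at(m.pX, m.N, row, c) * betag[c];
        for (int c = 0; c < d.r; ++c) mu += at(m.pZ, m.N, row, c) * w.b[c];
        double res = m.py[row] - mu;
        ll += -0.5 * LOG2PI - 0.5 * w.lsig[g] - 0.5 * res * res / w.sigma2[g];
      }
      double wg_lin = 0.0;
      for (int c = 0; c < d.q; ++c) wg_lin += at(m.pWt, d.n, i, c) * w.gam[g * d.q + c];
      double H = 0.0;
      for (int k = 0; k < d.nq; ++k) {
        int row = i * d.nq + k;
        if (m.pwq[row] == 0.0) continue;
        double mua = 0.0;
        if (d.assoc != 0) {
          for (int c = 0; c < d.p; ++c) mua += at(m.pXqa, nqn, row, c) * betag[c];
          for (int c = 0; c < d.r; ++c) mua += at(m.pZqa, nqn, row, c) * w.b[c];
        }
        H += m.pwq[row] * std::exp(w.lphi0[g] + (w.phi0[g] - 1.0) * m.plogsq[row]
                                   + w.phi1[g] + wg_lin + w.alpha[g] * mua);
      }
      ll -= H;
      if (m.pdelta[i] == 1) {
        double mua = 0.0;
        if (d.assoc != 0) {
          for (int c = 0; c < d.p; ++c) mua += at(m.pXTa, d.n, i, c) * betag[c];
          for (int c = 0; c < d.r; ++c) mua += at(m.pZTa, d.n, i, c) * w.b[c];
        }
        ll += w.lphi0[g] + (w.phi0[g] - 1.0) * m.plogT[i] + w.phi1[g]
            + wg_lin + w.alpha[g] * mua;
      }
      out(i, g) = ll;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Compiled No-U-Turn sampler specialized to the model above. Mirrors the
// generic R implementation (same algorithm, same adaptation schedule) but
// evaluates the density without leaving C++. Uses R's RNG so that results
// are reproducible under set.seed().

struct NutsState {
  const MD* m;
  Work w;
  std::vector<double> minv;
  double eps;
  int n_par;
  double lp_eval(const double* q, double* grad) {
    return lp_grad_core(q, *m, w, grad, nullptr);
  }
  double kinetic(const std::vector<double>& p) {
    double k = 0.0;
    for (int i = 0; i < n_par; ++i) k += p[i] * p[i] * minv[i];
    return 0.5 * k;
  }
  void leapfrog(std::vector<double>& q, std::vector<double>& p,
                std::vector<double>& grad, double& lp, double veps) {
    for (int i = 0; i < n_par; ++i) p[i] += 0.5 * veps * grad[i];
    for (int i = 0; i < n_par; ++i) q[i] += veps * minv[i] * p[i];
    lp = lp_eval(q.data(), grad.data());
    if (!R_FINITE(lp)) { return; }
    for (int i = 0; i < n_par; ++i) p[i] += 0.5 * veps * grad[i];
  }
};

struct Tree {
  std::vector<double> qm, pm, gm, qp, pp, gp, qn;
  double lpm, lpp, lpn;
  double alpha; int n, nalpha; bool s, div;
};

static const double DIV_MAX = 1000.0;

static void build_tree(NutsState& st, Tree& t, std::vector<double>& q,
                       std::vector<double>& p, std::vector<double>& grad,
                       double lp, double logu, int v, int j, double H0) {
  if (j == 0) {
    t.qm = q; t.pm = p; t.gm = grad; t.lpm = lp;
    st.leapfrog(t.qm, t.pm, t.gm, t.lpm, v * st.eps);
    double Hn = R_FINITE(t.lpm) ? t.lpm - st.kinetic(t.pm) : R_NegInf;
    t.n = (logu <= Hn) ? 1 : 0;
    t.div = (logu - DIV_MAX) > Hn;
    t.s = !t.div;
    double a = std::exp(Hn - H0);
    t.alpha = (R_FINITE(a) && a < 1.0) ? a : (R_FINITE(Hn) ? 1.0 : 0.0);
    t.nalpha = 1;
    t.qp = t.qm; t.pp = t.pm; t.gp = t.gm; t.lpp = t.lpm;
    t.qn = t.qm; t.lpn = t.lpm;
    return;
  }
  build_tree(st, t, q, p, grad, lp, logu, v, j - 1, H0);
  if (t.s) {
    Tree t2;
    if (v == -1) {
      build_tree(st, t2, t.qm, t.pm, t.gm, t.lpm, logu, v, j - 1, H0);
      t.qm = t2.qm; t.pm = t2.pm; t.gm = t2.gm; t.lpm = t2.lpm;
    } else {
      build_tree(st, t2, t.qp, t.pp, t.gp, t.lpp, logu, v, j - 1, H0);
      t.qp = t2.qp; t.pp = t2.pp; t.gp = t2.gp; t.lpp = t2.lpp;
    }
    if (t2.n > 0 && unif_rand() < (double)t2.n / (t.n + t2.n)) {
      t.qn = t2.qn; t.lpn = t2.lpn;
    }
    double dot_m = 0.0, dot_p = 0.0;
    for (int i = 0; i < st.n_par; ++i) {
      double dq = t.qp[i] - t.qm[i];
      dot_m += dq * st.minv[i] * t.pm[i];
      dot_p += dq * st.minv[i] * t.pp[i];
    }
    t.s = t2.s && dot_m >= 0 && dot_p >= 0;
    t.n += t2.n;
    t.alpha += t2.alpha;
    t.nalpha += t2.nalpha;
    t.div = t.div || t2.div;
  }
}

static double find_eps(NutsState& st, std::vector<double>& q,
                       std::vector<double>& grad, double lp) {
  int d = st.n_par;
  double eps = 1.0;
  std::vector<double> p(d);
  for (int i = 0; i < d; ++i) p[i] = norm_rand() / std::sqrt(st.minv[i]);
  double H0 = lp - st.kinetic(p);
  std::vector<double> q1, p1, g1; double lp1;
  auto try_eps = [&](double e) {
    q1 = q; p1 = p; g1 = grad; lp1 = lp;
    st.eps = e;
    st.leapfrog(q1, p1, g1, lp1, e);
    return R_FINITE(lp1) ? lp1 - st.kinetic(p1) : R_NegInf;
  };
  double H1 = try_eps(eps);
  if (!R_FINITE(H1)) {
    for (int k = 0; k < 40 && !R_FINITE(H1); ++k) { eps /= 2; H1 = try_eps(eps); }
    if (!R_FINITE(H1)) return 1e-6;
  }
  double a = (H1 - H0 > std::log(0.5)) ? 1.0 : -1.0;
  for (int k = 0; k < 40; ++k) {
    eps *= std::pow(2.0, a);
    H1 = try_eps(eps);
    if (!R_FINITE(H1)) H1 = R_NegInf;
    if (a * (H1 - H0) < a * std::log(0.5)) break;
  }
  return eps;
}

// [[Rcpp::export]]
List jlcm_nuts_cpp(List md, NumericVector init, int iter, int warmup,
                   int thin, double adapt_delta, int max_treedepth) {
  MD m = parse_md(md);
  NutsState st;
  st.m = &m; st.w.init(m.d); st.n_par = m.d.n_par;
  st.minv.assign(st.n_par, 1.0);
  int d = st.n_par;
  if ((int)init.size() != d) stop("init has length %d, expected %d",
                                  (int)init.size(), d);

  std::vector<double> q(init.begin(), init.end());
  std::vector<double> grad(d);
  double lp = st.lp_eval(q.data(), grad.data());
  if (!R_FINITE(lp)) stop("initial point has non-finite log density");

  st.eps = find_eps(st, q, grad, lp);
  double mu = std::log(10 * st.eps), log_eps_bar = 0.0, Hbar = 0.0;
  int m_adapt = 0;
  const double da_gamma = 0.05, da_t0 = 10.0, da_kappa = 0.75;

  int w_init = std::max(5, (int)std::floor(0.15 * warmup));
  int w_term = std::max(5, (int)std::floor(0.10 * warmup));
  int win_lo = w_init + 1, win_hi = warmup - w_term;
  int wlen = 25;
  int next_win = (win_hi > win_lo) ? std::min(win_lo + wlen - 1, win_hi) : -1;
  std::vector<double> wsum(d, 0.0), wsum2(d, 0.0);
  int wn = 0;

  int n_keep = (iter - warmup) / thin;
  NumericMatrix draws(n_keep, d);
  NumericVector lp_out(n_keep), lpj_out(n_keep), acc_out(n_keep);
  IntegerVector td_out(n_keep), div_out(n_keep);
  int n_div_total = 0, keep_i = 0;

  std::vector<double> p0(d);
  Tree tr;
  for (int it = 1; it <= iter; ++it) {
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
    for (int i = 0; i < d; ++i) p0[i] = norm_rand() / std::sqrt(st.minv[i]);
    double H0 = lp - st.kinetic(p0);
    double logu = H0 - exp_rand();
    std::vector<double> qm = q, pm = p0, gm = grad;
    std::vector<double> qp = q, pp = p0, gp = grad;
    std::vector<double> qn = q;
    double lpm = lp, lpp = lp, lpn = lp;
    int n_tot = 1, j = 0;
    bool s = true, diverged = false;
    double alpha_sum = 0.0; int nalpha_sum = 0;
    while (s && j < max_treedepth) {
      int v = (unif_rand() < 0.5) ? -1 : 1;
      if (v == -1) {
        build_tree(st, tr, qm, pm, gm, lpm, logu, v, j, H0);
        qm = tr.qm; pm = tr.pm; gm = tr.gm; lpm = tr.lpm;
      } else {
        build_tree(st, tr, qp, pp, gp, lpp, logu, v, j, H0);
        qp = tr.qp; pp = tr.pp; gp = tr.gp; lpp = tr.lpp;
      }
      if (tr.s && tr.n > 0 &&
          unif_rand() < std::min(1.0, (double)tr.n / n_tot)) {
        qn = tr.qn; lpn = tr.lpn;
      }
      n_tot += tr.n;
      alpha_sum += tr.alpha;
      nalpha_sum += tr.nalpha;
      diverged = diverged || tr.div;
      double dot_m = 0.0, dot_p = 0.0;
      for (int i = 0; i < d; ++i) {
        double dq = qp[i] - qm[i];
        dot_m += dq * st.minv[i] * pm[i];
        dot_p += dq * st.minv[i] * pp[i];
      }
      s = tr.s && dot_m >= 0 && dot_p >= 0;
      ++j;
    }
    if (qn != q) {
      q = qn;
      lp = st.lp_eval(q.data(), grad.data());
    }
    double accept_stat = (nalpha_sum > 0) ? alpha_sum / nalpha_sum : 0.0;
    if (diverged) ++n_div_total;

    if (it <= warmup) {
      ++m_adapt;
      double frac = 1.0 / (m_adapt + da_t0);
      Hbar = (1 - frac) * Hbar + frac * (adapt_delta - accept_stat);
      double log_eps = mu - std::sqrt((double)m_adapt) / da_gamma * Hbar;
      log_eps_bar = std::pow((double)m_adapt, -da_kappa) * log_eps +
        (1 - std::pow((double)m_adapt, -da_kappa)) * log_eps_bar;
      st.eps = std::exp(log_eps);
      if (it >= win_lo && it <= win_hi) {
        for (int i = 0; i < d; ++i) { wsum[i] += q[i]; wsum2[i] += q[i] * q[i]; }
        ++wn;
        if (it == next_win || it == win_hi) {
          if (wn >= 10) {
            for (int i = 0; i < d; ++i) {
              double v_est = (wsum2[i] - wsum[i] * wsum[i] / wn) / (wn - 1);
              double mv = v_est * wn / (wn + 5.0) + 1e-3 * 5.0 / (wn + 5.0);
              st.minv[i] = (R_FINITE(mv) && mv > 0) ? mv : 1e-3;
            }
            st.eps = find_eps(st, q, grad, lp);
            mu = std::log(10 * st.eps); log_eps_bar = 0.0; Hbar = 0.0;
            m_adapt = 0;
          }
          std::fill(wsum.begin(), wsum.end(), 0.0);
          std::fill(wsum2.begin(), wsum2.end(), 0.0);
          wn = 0;
          wlen *= 2;
          next_win = std::min(it + wlen, win_hi);
        }
      }
      if (it == warmup) st.eps = std::exp(log_eps_bar);
    } else {
      int k = it - warmup;
      if (k % thin == 0 && keep_i < n_keep) {
        for (int i = 0; i < d; ++i) draws(keep_i, i) = q[i];
        double lpj;
        lp_grad_core(q.data(), m, st.w, nullptr, &lpj);
        lp_out[keep_i] = lp;
        lpj_out[keep_i] = lpj;
        div_out[keep_i] = diverged ? 1 : 0;
        td_out[keep_i] = j;
        acc_out[keep_i] = accept_stat;
        ++keep_i;
      }
    }
  }

  return List::create(_["draws"] = draws, _["lp"] = lp_out,
                      _["lp_joint"] = lpj_out,
                      _["divergent"] = div_out, _["treedepth"] = td_out,
                      _["accept_stat"] = acc_out, _["step_size"] = st.eps,
                      _["inv_mass"] = NumericVector(st.minv.begin(), st.minv.end()),
                      _["n_divergent"] = n_div_total);
}
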