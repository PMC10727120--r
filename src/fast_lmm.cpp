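// Fast random-intercept REML, 1-D TFCE and the bootstrap cluster null.
//
// The mixed model handled here is y = X b + u_g + e with a single random
// intercept per participant, u ~ N(0, tau2), e ~ N(0, sigma2). For fixed
// gamma = tau2/sigma2 the GLS solution has closed form through per-group
// rank-1 updates (V_g^-1 = I - gamma/(1+gamma*m_g) J), so REML reduces to
// a 1-D profiled criterion in gamma, optimized by golden section on
// log(gamma). This is the same criterion lme4::lmer minimizes; the R test
// suite checks agreement of the t statistics with lmer to 1e-4.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct RIData {
  arma::mat XtX;
  arma::vec Xty;
  double yty;
  unsigned n, p;
  arma::mat sx;             // p x G group sums of X rows
  arma::vec sy, m;          // group sums of y, group sizes
};

static void make_ridata(const arma::mat& X, const arma::vec& y,
                        const arma::uvec& g, unsigned G, RIData& D) {
  unsigned n = X.n_rows, p = X.n_cols;
  D.n = n;
  D.p = p;
  D.XtX.zeros(p, p);
  D.Xty.zeros(p);
  D.yty = 0.0;
  D.sx.zeros(p, G);
  D.sy.zeros(G);
  D.m.zeros(G);
  for (unsigned i = 0; i < n; ++i) {
    unsigned j = g(i);
    double yi = y(i);
    D.yty += yi * yi;
    double* sxj = D.sx.colptr(j);
    for (unsigned a = 0; a < p; ++a) {
      double xa = X(i, a);
      sxj[a] += xa;
      D.Xty(a) += xa * yi;
      for (unsigned b = 0; b <= a; ++b) D.XtX(a, b) += xa * X(i, b);
    }
    D.sy(j) += yi;
    D.m(j) += 1.0;
  }
  for (unsigned a = 0; a < p; ++a)
    for (unsigned b = a + 1; b < p; ++b) D.XtX(a, b) = D.XtX(b, a);
}

// solve A x = b for small symmetric positive-definite A without LAPACK;
// also returns log|A|. Falls back to Armadillo above p = 3.
static bool solve_spd(const arma::mat& A, const arma::vec& b, arma::vec& x,
                      double& logdet) {
  unsigned p = A.n_rows;
  if (p == 1) {
    if (!(A(0, 0) > 0)) return false;
    logdet = std::log(A(0, 0));
    x.set_size(1);
    x(0) = b(0) / A(0, 0);
    return true;
  }
  if (p == 2) {
    double det = A(0, 0) * A(1, 1) - A(0, 1) * A(1, 0);
    if (!(det > 0) || !(A(0, 0) > 0)) return false;
    logdet = std::log(det);
    x.set_size(2);
    x(0) = (A(1, 1) * b(0) - A(0, 1) * b(1)) / det;
    x(1) = (A(0, 0) * b(1) - A(1, 0) * b(0)) / det;
    return true;
  }
  if (p == 3) {
    double a = A(0, 0), bb = A(0, 1), c = A(0, 2);
    double d = A(1, 0), e = A(1, 1), f = A(1, 2);
    double g = A(2, 0), h = A(2, 1), i = A(2, 2);
    double det = a * (e * i - f * h) - bb * (d * i - f * g) + c * (d * h - e * g);
    if (!(det > 0) || !(a > 0)) return false;
    logdet = std::log(det);
    x.set_size(3);
    // adjugate * b
    x(0) = ((e * i - f * h) * b(0) + (c * h - bb * i) * b(1) + (bb * f - c * e) * b(2)) / det;
    x(1) = ((f * g - d * i) * b(0) + (a * i - c * g) * b(1) + (c * d - a * f) * b(2)) / det;
    x(2) = ((d * h - e * g) * b(0) + (bb * g - a * h) * b(1) + (a * e - bb * d) * b(2)) / det;
    return true;
  }
  if (!arma::solve(x, A, b, arma::solve_opts::no_approx)) return false;
  double val, sign;
  arma::log_det(val, sign, A);
  if (sign <= 0) return false;
  logdet = val;
  return true;
}

// diagonal of A^-1 for small SPD A (fallback to full inverse otherwise)
static bool invdiag_spd(const arma::mat& A, arma::vec& d) {
  unsigned p = A.n_rows;
  d.set_size(p);
  if (p == 1) {
    if (!(A(0, 0) > 0)) return false;
    d(0) = 1.0 / A(0, 0);
    return true;
  }
  if (p == 2) {
    double det = A(0, 0) * A(1, 1) - A(0, 1) * A(1, 0);
    if (!(det > 0)) return false;
    d(0) = A(1, 1) / det;
    d(1) = A(0, 0) / det;
    return true;
  }
  if (p == 3) {
    double a = A(0, 0), bb = A(0, 1), c = A(0, 2);
    double dd = A(1, 0), e = A(1, 1), f = A(1, 2);
    double g = A(2, 0), h = A(2, 1), i = A(2, 2);
    double det = a * (e * i - f * h) - bb * (dd * i - f * g) + c * (dd * h - e * g);
    if (!(det > 0)) return false;
    d(0) = (e * i - f * h) / det;
    d(1) = (a * i - c * g) / det;
    d(2) = (a * e - bb * dd) / det;
    return true;
  }
  arma::mat Ai;
  if (!arma::inv_sympd(Ai, arma::symmatu(A)) && !arma::inv(Ai, A)) return false;
  d = Ai.diag();
  return true;
}

// profiled -2 REML log-likelihood (up to an additive constant)
static double reml_dev(double gamma, const RIData& D,
                       arma::mat& A, arma::vec& bv, arma::vec& beta,
                       double& rss) {
  A = D.XtX;
  bv = D.Xty;
  unsigned p = D.p;
  double q = D.yty, logdetV = 0.0;
  for (unsigned j = 0; j < D.m.n_elem; ++j) {
    double mj = D.m(j);
    if (mj == 0.0) continue;
    double c = gamma / (1.0 + gamma * mj);
    logdetV += std::log1p(gamma * mj);
    const double* sxj = D.sx.colptr(j);
    double syj = D.sy(j);
    for (unsigned a = 0; a < p; ++a) {
      double ca = c * sxj[a];
      bv(a) -= ca * syj;
      for (unsigned b = 0; b <= a; ++b) A(a, b) -= ca * sxj[b];
    }
    q -= c * syj * syj;
  }
  for (unsigned a = 0; a < p; ++a)
    for (unsigned b = a + 1; b < p; ++b) A(a, b) = A(b, a);
  double logdetA;
  if (!solve_spd(A, bv, beta, logdetA)) return NA_REAL;
  rss = q - arma::dot(beta, bv);
  if (!(rss > 0)) rss = 1e-300;
  return (double)(D.n - D.p) * std::log(rss) + logdetV + logdetA;
}

struct RIFit {
  arma::vec beta, se;
  double sigma2, tau2;
  bool ok;
};

static RIFit fit_ri(const arma::mat& X, const arma::vec& y,
                    const arma::uvec& g, unsigned G, double tol) {
  RIFit out; out.ok = false;
  if (X.n_rows <= X.n_cols + 1) return out;
  RIData D;
  make_ridata(X, y, g, G, D);
  arma::mat A; arma::vec bv, beta; double rss;
  // golden-section search on theta = log(gamma)
  const double gr = 0.6180339887498949;
  double lo = -18.0, hi = 12.0;
  double x1 = hi - gr * (hi - lo), x2 = lo + gr * (hi - lo);
  double f1 = reml_dev(std::exp(x1), D, A, bv, beta, rss);
  double f2 = reml_dev(std::exp(x2), D, A, bv, beta, rss);
  if (!std::isfinite(f1) || !std::isfinite(f2)) return out;
  while (hi - lo > tol) {
    if (f1 < f2) {
      hi = x2; x2 = x1; f2 = f1;
      x1 = hi - gr * (hi - lo);
      f1 = reml_dev(std::exp(x1), D, A, bv, beta, rss);
    } else {
      lo = x1; x1 = x2; f1 = f2;
      x2 = lo + gr * (hi - lo);
      f2 = reml_dev(std::exp(x2), D, A, bv, beta, rss);
    }
    if (!std::isfinite(f1) || !std::isfinite(f2)) return out;
  }
  double theta = 0.5 * (lo + hi);
  double gamma = std::exp(theta);
  // compare interior optimum against the gamma -> 0 boundary
  double fopt = reml_dev(gamma, D, A, bv, beta, rss);
  double f0 = reml_dev(0.0, D, A, bv, beta, rss);
  if (std::isfinite(f0) && f0 <= fopt) gamma = 0.0;
  double dev = reml_dev(gamma, D, A, bv, beta, rss);
  if (!std::isfinite(dev)) return out;
  double sigma2 = rss / (double)(D.n - D.p);
  arma::vec adiag;
  if (!invdiag_spd(A, adiag)) return out;
  out.beta = beta;
  out.se = arma::sqrt(sigma2 * adiag);
  out.sigma2 = sigma2;
  out.tau2 = gamma * sigma2;
  out.ok = true;
  return out;
}

// [[Rcpp::export]]
List reml_ri_cpp(const arma::vec& y, const arma::mat& X,
                 const arma::uvec& g, int G, double tol = 1e-7) {
  RIFit f = fit_ri(X, y, g, (unsigned)G, tol);
  if (!f.ok)
    return List::create(_["ok"] = false);
  return List::create(
    _["ok"] = true,
    _["beta"] = f.beta,
    _["se"] = f.se,
    _["t"] = f.beta / f.se,
    _["sigma2"] = f.sigma2,
    _["tau2"] = f.tau2);
}

// Assemble the per-window design and fit; returns false when the window is
// degenerate (too few rows, constant predictor, solver failure).
static bool window_fit(const arma::rowvec& yrow, const arma::rowvec& prow,
                       const arma::mat& C, const arma::uvec& g, unsigned G,
                       double tol, double& t_out, double& est_out,
                       double& se_out, int& n_out) {
  unsigned n = yrow.n_elem, q = C.n_cols;
  std::vector<unsigned> idx;
  idx.reserve(n);
  for (unsigned i = 0; i < n; ++i) {
    if (std::isfinite(yrow(i)) && std::isfinite(prow(i))) {
      bool okc = true;
      for (unsigned j = 0; j < q; ++j)
        if (!std::isfinite(C(i, j))) { okc = false; break; }
      if (okc) idx.push_back(i);
    }
  }
  unsigned m = idx.size();
  if (m < q + 4) return false;
  arma::mat X(m, 2 + q);
  arma::vec y(m);
  arma::uvec gg(m);
  double pmin = R_PosInf, pmax = R_NegInf;
  for (unsigned r = 0; r < m; ++r) {
    unsigned i = idx[r];
    X(r, 0) = 1.0;
    X(r, 1) = prow(i);
    for (unsigned j = 0; j < q; ++j) X(r, 2 + j) = C(i, j);
    y(r) = yrow(i);
    gg(r) = g(i);
    pmin = std::min(pmin, prow(i));
    pmax = std::max(pmax, prow(i));
  }
  if (!(pmax > pmin)) return false;
  RIFit f = fit_ri(X, y, gg, G, tol);
  if (!f.ok || !std::isfinite(f.se(1)) || f.se(1) <= 0) return false;
  est_out = f.beta(1);
  se_out = f.se(1);
  t_out = f.beta(1) / f.se(1);
  n_out = (int)m;
  return true;
}

// [[Rcpp::export]]
List lmm_t_series_cpp(const arma::mat& Y, const arma::mat& P,
                      const arma::mat& C, const arma::uvec& g, int G,
                      double tol = 1e-6) {
  unsigned W = Y.n_rows;
  NumericVector t(W, NA_REAL), est(W, NA_REAL), se(W, NA_REAL);
  IntegerVector nobs(W, NA_INTEGER);
  for (unsigned w = 0; w < W; ++w) {
    double tv, ev, sv; int nv;
    if (window_fit(Y.row(w), P.row(w), C, g, (unsigned)G, tol, tv, ev, sv, nv)) {
      t[w] = tv; est[w] = ev; se[w] = sv; nobs[w] = nv;
    }
  }
  return List::create(_["t"] = t, _["estimate"] = est, _["se"] = se,
                      _["n_obs"] = nobs);
}

// 1-D TFCE, identical algorithm to the R reference tfce_1d()
static void tfce1d(const arma::vec& x, double E, double H, int nsteps,
                   arma::vec& score) {
  unsigned n = x.n_elem;
  score.zeros(n);
  double mx = x.max();
  if (!(mx > 0)) return;
  double dh = mx / (double)nsteps;
  for (double h = dh; h <= mx + 1e-12; h += dh) {
    unsigned i = 0;
    while (i < n) {
      if (x(i) >= h - 1e-12) {
        unsigned j = i;
        while (j + 1 < n && x(j + 1) >= h - 1e-12) ++j;
        double add = std::pow((double)(j - i + 1), E) * std::pow(h, H) * dh;
        for (unsigned k2 = i; k2 <= j; ++k2) score(k2) += add;
        i = j + 1;
      } else ++i;
    }
  }
}

// [[Rcpp::export]]
NumericVector tfce_1d_cpp(const arma::vec& x, double E = 0.5, double H = 2.0,
                          int nsteps = 100) {
  arma::vec xx = x;
  for (unsigned i = 0; i < xx.n_elem; ++i)
    if (!std::isfinite(xx(i))) xx(i) = 0.0;
  arma::vec s;
  tfce1d(xx, E, H, nsteps, s);
  return wrap(s);
}

// Specialized intercept+predictor (p = 2) REML fit on compacted arrays,
// avoiding all heap allocation inside the bootstrap loop. Returns the
// predictor t statistic (NA on degeneracy). Inputs are per-window
// compacted vectors of y, x and group ids plus precomputed y-side stats.
struct P2Work {
  std::vector<double> sx, sy, m;  // per-group accumulators (size G)
};

static double reml_dev_p2(double gamma, double n_eff,
                          double a11_0, double a12_0, double a22_0,
                          double b0_0, double b1_0, double q_0,
                          const double* sx, const double* sy,
                          const double* m, unsigned G,
                          double& beta1, double& se1) {
  double a11 = a11_0, a12 = a12_0, a22 = a22_0;
  double b0 = b0_0, b1 = b1_0, q = q_0, logdetV = 0.0;
  for (unsigned j = 0; j < G; ++j) {
    double mj = m[j];
    if (mj == 0.0) continue;
    double c = gamma / (1.0 + gamma * mj);
    logdetV += std::log1p(gamma * mj);
    a11 -= c * mj * mj;
    a12 -= c * mj * sx[j];
    a22 -= c * sx[j] * sx[j];
    b0 -= c * mj * sy[j];
    b1 -= c * sx[j] * sy[j];
    q -= c * sy[j] * sy[j];
  }
  double det = a11 * a22 - a12 * a12;
  if (!(det > 0) || !(a11 > 0)) return NA_REAL;
  double beta0 = (a22 * b0 - a12 * b1) / det;
  beta1 = (a11 * b1 - a12 * b0) / det;
  double rss = q - beta0 * b0 - beta1 * b1;
  if (!(rss > 0)) rss = 1e-300;
  double sigma2 = rss / (n_eff - 2.0);
  se1 = std::sqrt(sigma2 * a11 / det);
  return (n_eff - 2.0) * std::log(rss) + logdetV + std::log(det);
}

static double fit_t_p2(const double* y, const double* x, const unsigned* gid,
                       unsigned m, unsigned G, P2Work& W, double tol) {
  if (m < 4) return NA_REAL;
  std::fill(W.sx.begin(), W.sx.end(), 0.0);
  std::fill(W.sy.begin(), W.sy.end(), 0.0);
  std::fill(W.m.begin(), W.m.end(), 0.0);
  double sxt = 0, sxx = 0, syt = 0, sxy = 0, syy = 0;
  double xmin = R_PosInf, xmax = R_NegInf;
  for (unsigned i = 0; i < m; ++i) {
    double xi = x[i], yi = y[i];
    sxt += xi; sxx += xi * xi; syt += yi; sxy += xi * yi; syy += yi * yi;
    W.sx[gid[i]] += xi; W.sy[gid[i]] += yi; W.m[gid[i]] += 1.0;
    xmin = std::min(xmin, xi); xmax = std::max(xmax, xi);
  }
  if (!(xmax > xmin)) return NA_REAL;
  double n_eff = (double)m;
  double beta1, se1;
  const double gr = 0.6180339887498949;
  double lo = -18.0, hi = 12.0;
  double x1 = hi - gr * (hi - lo), x2 = lo + gr * (hi - lo);
  double f1 = reml_dev_p2(std::exp(x1), n_eff, n_eff, sxt, sxx, syt, sxy, syy,
                          W.sx.data(), W.sy.data(), W.m.data(), G, beta1, se1);
  double f2 = reml_dev_p2(std::exp(x2), n_eff, n_eff, sxt, sxx, syt, sxy, syy,
                          W.sx.data(), W.sy.data(), W.m.data(), G, beta1, se1);
  if (!std::isfinite(f1) || !std::isfinite(f2)) return NA_REAL;
  while (hi - lo > tol) {
    if (f1 < f2) {
      hi = x2; x2 = x1; f2 = f1;
      x1 = hi - gr * (hi - lo);
      f1 = reml_dev_p2(std::exp(x1), n_eff, n_eff, sxt, sxx, syt, sxy, syy,
                       W.sx.data(), W.sy.data(), W.m.data(), G, beta1, se1);
    } else {
      lo = x1; x1 = x2; f1 = f2;
      x2 = lo + gr * (hi - lo);
      f2 = reml_dev_p2(std::exp(x2), n_eff, n_eff, sxt, sxx, syt, sxy, syy,
                       W.sx.data(), W.sy.data(), W.m.data(), G, beta1, se1);
    }
    if (!std::isfinite(f1) || !std::isfinite(f2)) return NA_REAL;
  }
  double gamma = std::exp(0.5 * (lo + hi));
  double fopt = reml_dev_p2(gamma, n_eff, n_eff, sxt, sxx, syt, sxy, syy,
                            W.sx.data(), W.sy.data(), W.m.data(), G, beta1, se1);
  double b1b, s1b;
  double f0 = reml_dev_p2(0.0, n_eff, n_eff, sxt, sxx, syt, sxy, syy,
                          W.sx.data(), W.sy.data(), W.m.data(), G, b1b, s1b);
  if (std::isfinite(f0) && f0 <= fopt) { beta1 = b1b; se1 = s1b; }
  else if (!std::isfinite(fopt)) return NA_REAL;
  if (!(se1 > 0) || !std::isfinite(se1)) return NA_REAL;
  return beta1 / se1;
}

// Bootstrap (or permutation) null of the extreme TFCE score. Each rep
// resamples the predictor time courses across recordings (columns of P),
// keeping outcome time courses and covariates attached to their
// recordings, refits the mixed model in every window, orients the t series
// along the test tail, enhances it and records the maximum score. Uses the
// R RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List bootstrap_max_tfce_cpp(const arma::mat& Y, const arma::mat& P,
                            const arma::mat& C, const arma::uvec& g, int G,
                            int reps, int tail, double E = 0.5, double H = 2.0,
                            int nsteps = 100, bool permute = false,
                            double tol = 1e-4) {
  unsigned W = Y.n_rows, n = Y.n_cols;
  NumericVector maxima(reps, NA_REAL);
  int redraws = 0;
  arma::uvec idx(n);
  arma::vec tser(W), score;
  // fast path: no covariates and fully-finite predictor matrix
  bool fast = (C.n_cols == 0) && P.is_finite();
  std::vector<std::vector<unsigned>> wmask(W);
  std::vector<std::vector<double>> wy(W);
  std::vector<std::vector<unsigned>> wg(W);
  P2Work Wk;
  std::vector<double> xbuf(n);
  if (fast) {
    Wk.sx.assign(G, 0.0); Wk.sy.assign(G, 0.0); Wk.m.assign(G, 0.0);
    for (unsigned w = 0; w < W; ++w) {
      for (unsigned i = 0; i < n; ++i) {
        if (std::isfinite(Y(w, i))) {
          wmask[w].push_back(i);
          wy[w].push_back(Y(w, i));
          wg[w].push_back((unsigned)g(i));
        }
      }
    }
  }
  for (int r = 0; r < reps; ++r) {
    bool okdraw = false;
    for (int attempt = 0; attempt < 1000 && !okdraw; ++attempt) {
      if (permute) {
        for (unsigned i = 0; i < n; ++i) idx(i) = i;
        for (unsigned i = n - 1; i > 0; --i) {
          unsigned j = (unsigned)std::floor(unif_rand() * (double)(i + 1));
          if (j > i) j = i;
          std::swap(idx(i), idx(j));
        }
      } else {
        for (unsigned i = 0; i < n; ++i) {
          unsigned j = (unsigned)std::floor(unif_rand() * (double)n);
          if (j >= n) j = n - 1;
          idx(i) = j;
        }
      }
      // reject draws whose resampled predictor is constant
      double pmin = R_PosInf, pmax = R_NegInf;
      for (unsigned i = 0; i < n; ++i) {
        double v = P(0, idx(i));
        if (std::isfinite(v)) {
          pmin = std::min(pmin, v);
          pmax = std::max(pmax, v);
        }
      }
      if (pmax > pmin) okdraw = true; else ++redraws;
    }
    if (!okdraw) stop("could not draw a non-degenerate bootstrap resample");
    if (fast) {
      for (unsigned w = 0; w < W; ++w) {
        const std::vector<unsigned>& mk = wmask[w];
        unsigned m = mk.size();
        for (unsigned i = 0; i < m; ++i) xbuf[i] = P(w, idx(mk[i]));
        double tv = fit_t_p2(wy[w].data(), xbuf.data(), wg[w].data(), m,
                             (unsigned)G, Wk, tol);
        tser(w) = std::isfinite(tv) ? (double)tail * tv : 0.0;
      }
    } else {
      arma::mat Pr(W, n);
      for (unsigned i = 0; i < n; ++i) Pr.col(i) = P.col(idx(i));
      for (unsigned w = 0; w < W; ++w) {
        double tv, ev, sv; int nv;
        if (window_fit(Y.row(w), Pr.row(w), C, g, (unsigned)G, tol, tv, ev, sv, nv))
          tser(w) = (double)tail * tv;
        else
          tser(w) = 0.0;
      }
    }
    tfce1d(tser, E, H, nsteps, score);
    maxima[r] = score.max();
  }
  return List::create(_["max"] = maxima, _["redraws"] = redraws);
}

// ---- simulation and sweep kernels -----------------------------------------
// These mirror the R reference implementations (fit_window_ar1 / order_eigs
// and the latent AR forward model); the test suite checks agreement.

// closed-form eigen of a real 2x2; returns moduli/vectors ordered by
// component association (see order_eigs() in R)
static void order_eigs_2x2(double a, double b, double c, double d,
                           double* mod, double* vec, bool& cplx) {
  double tr = a + d, det = a * d - b * c;
  double disc = tr * tr / 4.0 - det;
  double lr[2], mods[2];
  if (disc >= 0) {
    double s = std::sqrt(disc);
    lr[0] = tr / 2 + s; lr[1] = tr / 2 - s;
    mods[0] = std::fabs(lr[0]); mods[1] = std::fabs(lr[1]);
    cplx = false;
  } else {
    double s = std::sqrt(-disc);
    lr[0] = tr / 2; lr[1] = tr / 2;
    mods[0] = mods[1] = std::sqrt(lr[0] * lr[0] + s * s);
    cplx = true;
  }
  double V[2][2];
  for (int k = 0; k < 2; ++k) {
    double v0, v1;
    if (std::fabs(b) >= std::fabs(c) &&
        (std::fabs(b) > 1e-300 || std::fabs(lr[k] - a) > 1e-300)) {
      v0 = b; v1 = lr[k] - a;
    } else if (std::fabs(c) > 1e-300 || std::fabs(lr[k] - d) > 1e-300) {
      v0 = lr[k] - d; v1 = c;
    } else {
      v0 = (k == 0); v1 = (k == 1);
    }
    double nv = std::sqrt(v0 * v0 + v1 * v1);
    if (nv > 0) { v0 /= nv; v1 /= nv; }
    V[0][k] = v0; V[1][k] = v1;
  }
  int claim0 = (std::fabs(V[0][0]) >= std::fabs(V[1][0])) ? 0 : 1;
  int claim1 = (std::fabs(V[0][1]) >= std::fabs(V[1][1])) ? 0 : 1;
  int ord[2];
  if (claim0 != claim1) {
    if (claim0 == 0) { ord[0] = 0; ord[1] = 1; } else { ord[0] = 1; ord[1] = 0; }
  } else {
    int p = claim0;
    int winner = (std::fabs(V[p][0]) >= std::fabs(V[p][1])) ? 0 : 1;
    if (p == 0) { ord[0] = winner; ord[1] = 1 - winner; }
    else { ord[0] = 1 - winner; ord[1] = winner; }
  }
  for (int k = 0; k < 2; ++k) {
    int j = ord[k];
    double v0 = V[0][j], v1 = V[1][j];
    double own = (k == 0) ? v0 : v1;
    if (own < 0) { v0 = -v0; v1 = -v1; }
    vec[k * 2 + 0] = v0; vec[k * 2 + 1] = v1;
    mod[k] = mods[j];
  }
}

// [[Rcpp::export]]
List sweep_dynamics_core_cpp(const arma::mat& a, const arma::mat& b,
                             int half, int step, int min_pairs) {
  unsigned n = a.n_rows, nt = a.n_cols;
  std::vector<double> aa(nt), ab(nt), bb(nt), c11(nt), c12(nt), c21(nt), c22(nt);
  for (unsigned t = 0; t + 1 < nt; ++t) {
    double saa = 0, sab = 0, sbb = 0, s11 = 0, s12 = 0, s21 = 0, s22 = 0;
    for (unsigned i = 0; i < n; ++i) {
      double at = a(i, t), bt = b(i, t), a1 = a(i, t + 1), b1 = b(i, t + 1);
      saa += at * at; sab += at * bt; sbb += bt * bt;
      s11 += a1 * at; s12 += a1 * bt; s21 += b1 * at; s22 += b1 * bt;
    }
    aa[t] = saa; ab[t] = sab; bb[t] = sbb;
    c11[t] = s11; c12[t] = s12; c21[t] = s21; c22[t] = s22;
  }
  std::vector<int> centers;
  for (int ci = half; ci + half < (int)nt; ci += step) centers.push_back(ci);
  unsigned nw = centers.size();
  NumericMatrix out(nw, 10);
  LogicalVector cflag(nw);
  IntegerVector npairs(nw), centers_out(nw);
  IntegerVector singular(nw);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (unsigned w = 0; w < nw; ++w) {
    int ci = centers[w];
    centers_out[w] = ci + 1;  // 1-based sample index
    int lo = ci - half, hi = ci + half - 1;
    int np = n * (hi - lo + 1);
    npairs[w] = np;
    cflag[w] = NA_LOGICAL;
    if (np < min_pairs) continue;
    double s11 = 0, s12 = 0, s22 = 0, y11 = 0, y12 = 0, y21 = 0, y22 = 0;
    for (int t = lo; t <= hi; ++t) {
      s11 += aa[t]; s12 += ab[t]; s22 += bb[t];
      y11 += c11[t]; y12 += c12[t]; y21 += c21[t]; y22 += c22[t];
    }
    double det = s11 * s22 - s12 * s12;
    double scale = std::max(s11 * s22, 1e-300);
    if (!(det > 1e-12 * scale)) { singular[w] = 1; continue; }
    double A11 = (y11 * s22 - y12 * s12) / det;
    double A12 = (y12 * s11 - y11 * s12) / det;
    double A21 = (y21 * s22 - y22 * s12) / det;
    double A22 = (y22 * s11 - y21 * s12) / det;
    double mod[2], vec[4]; bool cx;
    order_eigs_2x2(A11, A12, A21, A22, mod, vec, cx);
    out(w, 0) = A11; out(w, 1) = A12; out(w, 2) = A21; out(w, 3) = A22;
    out(w, 4) = mod[0]; out(w, 5) = mod[1];
    out(w, 6) = vec[0]; out(w, 7) = vec[1];
    out(w, 8) = vec[2]; out(w, 9) = vec[3];
    cflag[w] = cx;
  }
  return List::create(_["centers"] = centers_out, _["out"] = out,
                      _["complex"] = cflag, _["n_pairs"] = npairs,
                      _["singular"] = singular);
}

// latent AR(1) forward model + template + sensor mixing for one lock.
// Uses the R RNG (set.seed-reproducible). Amats: 2x2xnt (slice per sample,
// or a single slice for time-constant dynamics); R0: 2x2 upper-triangular
// factor with crossprod(R0) = stationary covariance; tpl: 2 x nt x ncond.
// [[Rcpp::export]]
arma::cube sim_lock_core_cpp(const arma::cube& Amats, const arma::mat& R0,
                             double noise_sd, const arma::mat& loadings,
                             const arma::cube& tpl, const arma::uvec& cidx,
                             double sensor_noise_sd) {
  unsigned n = cidx.n_elem, nt = tpl.n_cols, ns = loadings.n_rows;
  bool tv = (Amats.n_slices > 1);
  arma::mat x(n, 2, arma::fill::zeros), xn(n, 2);
  if (noise_sd > 0) {
    arma::mat E(n, 2);
    for (unsigned k = 0; k < 2; ++k)
      for (unsigned i = 0; i < n; ++i) E(i, k) = norm_rand();
    x = E * R0;
  }
  arma::cube outc(n, ns, nt);
  for (unsigned t = 0; t < nt; ++t) {
    if (t > 0) {
      const arma::mat& A = Amats.slice(tv ? t - 1 : 0);
      for (unsigned i = 0; i < n; ++i) {
        double x0 = x(i, 0), x1 = x(i, 1);
        xn(i, 0) = A(0, 0) * x0 + A(0, 1) * x1;
        xn(i, 1) = A(1, 0) * x0 + A(1, 1) * x1;
      }
      if (noise_sd > 0)
        for (unsigned k = 0; k < 2; ++k)
          for (unsigned i = 0; i < n; ++i)
            xn(i, k) += noise_sd * norm_rand();
      x = xn;
    }
    arma::mat& S = outc.slice(t);
    for (unsigned i = 0; i < n; ++i) {
      double l0 = x(i, 0) + tpl(0, t, cidx(i));
      double l1 = x(i, 1) + tpl(1, t, cidx(i));
      for (unsigned s = 0; s < ns; ++s)
        S(i, s) = loadings(s, 0) * l0 + loadings(s, 1) * l1;
    }
  }
  if (sensor_noise_sd > 0)
    for (auto it = outc.begin(); it != outc.end(); ++it)
      *it += sensor_noise_sd * norm_rand();
  return outc;
}

// test hook: the specialized p = 2 fit used inside the bootstrap fast path
// [[Rcpp::export]]
double lmm_t_p2_cpp(const arma::vec& y, const arma::vec& x,
                    const arma::uvec& g, int G, double tol = 1e-7) {
  P2Work W;
  W.sx.assign(G, 0.0); W.sy.assign(G, 0.0); W.m.assign(G, 0.0);
  std::vector<unsigned> gid(g.n_elem);
  for (unsigned i = 0; i < g.n_elem; ++i) gid[i] = (unsigned)g(i);
  return fit_t_p2(y.memptr(), x.memptr(), gid.data(), y.n_elem,
                  (unsigned)G, W, tol);
}
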