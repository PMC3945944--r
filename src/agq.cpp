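#include <Rcpp.h>
using namespace Rcpp;

// Marginal negative log-likelihood (and gradient) of a Poisson log-link model
// with a scalar Gaussian random intercept per cluster, integrated by adaptive
// Gauss-Hermite quadrature.
//
// Model: y_ij ~ Poisson(exp(eta_ij + sigma * b_i)), b_i ~ N(0, 1),
// eta = X beta. Rows must be sorted by cluster; cl_start/cl_end are 0-based
// half-open row ranges per cluster.
//
// The per-cluster log-integrand reduces to sufficient statistics
//   h_i(b) = A_i + sigma S_i b - T_i e^{sigma b} - b^2/2 - log sqrt(2 pi)
// with S_i = sum y, T_i = sum e^eta, A_i = sum y*eta = U_i . beta, so each
// quadrature node costs O(1) after one O(np) pass. The gradient uses
// Fisher's identity (posterior expectation of the score) evaluated with the
// same nodes. S (per-cluster response sums), U (p x m matrix of per-cluster
// sums of y * x) and lfact (sum log y!) are parameter-free and precomputed
// by the caller.
//
// par = (beta[0..p-1], sigma). gh_x / gh_logw are physicists' Gauss-Hermite
// nodes and log-weights.

// [[Rcpp::export]]
List agq_nll_cpp(NumericVector par, NumericMatrix X,
                 IntegerVector cl_start, IntegerVector cl_end,
                 NumericVector S, NumericMatrix U, double lfact,
                 NumericVector gh_x, NumericVector gh_logw,
                 bool want_grad) {
  const int n = X.nrow(), p = X.ncol(), m = cl_start.size(), K = gh_x.size();
  const double sigma = par[p];
  const double LOG_SQRT_2PI = 0.9189385332046727;

  std::vector<double> eta(n, 0.0), w(n);
  for (int r = 0; r < p; ++r) {
    const double br = par[r];
    const double* col = &X[0] + (size_t)r * n;
    for (int j = 0; j < n; ++j) eta[j] += col[j] * br;
  }
  for (int j = 0; j < n; ++j) {
    if (!R_finite(eta[j]))
      return List::create(_["nll"] = R_PosInf, _["grad"] = NumericVector(p + 1));
    w[j] = std::exp(eta[j]);
  }

  double loglik = -lfact;
  NumericVector grad(p + 1);
  std::vector<double> hk(K), bk(K), Ee(m), Tv(m);

  for (int i = 0; i < m; ++i) {
    const int a = cl_start[i], b = cl_end[i];
    double T = 0.0, A = 0.0;
    for (int j = a; j < b; ++j) T += w[j];
    for (int r = 0; r < p; ++r) A += U(r, i) * par[r];
    const double Si = S[i];
    Tv[i] = T;

    // Newton for the mode of h_i (strictly concave in b)
    double bh = 0.0, g2 = -1.0;
    for (int it = 0; it < 100; ++it) {
      double es = std::exp(sigma * bh);
      double g1 = sigma * (Si - T * es) - bh;
      g2 = -sigma * sigma * T * es - 1.0;
      double step = g1 / g2;
      if (step > 5.0) step = 5.0; else if (step < -5.0) step = -5.0;
      bh -= step;
      if (std::fabs(step) < 1e-12) break;
    }
    g2 = -sigma * sigma * T * std::exp(sigma * bh) - 1.0;
    const double sh = 1.0 / std::sqrt(-g2);

    double mx = R_NegInf;
    for (int k = 0; k < K; ++k) {
      const double bb = bh + M_SQRT2 * sh * gh_x[k];
      bk[k] = bb;
      const double h = A + sigma * Si * bb - T * std::exp(sigma * bb)
        - 0.5 * bb * bb - LOG_SQRT_2PI;
      hk[k] = gh_logw[k] + gh_x[k] * gh_x[k] + h;
      if (hk[k] > mx) mx = hk[k];
    }
    double se = 0.0;
    for (int k = 0; k < K; ++k) { hk[k] = std::exp(hk[k] - mx); se += hk[k]; }
    loglik += 0.5 * M_LN2 + std::log(sh) + mx + std::log(se);

    if (want_grad) {
      double ee = 0.0, Eb = 0.0, Ebe = 0.0;
      for (int k = 0; k < K; ++k) {
        const double pk = hk[k] / se;
        const double es = std::exp(sigma * bk[k]);
        ee += pk * es;
        Eb += pk * bk[k];
        Ebe += pk * bk[k] * es;
      }
      Ee[i] = ee;
      grad[p] += Si * Eb - T * Ebe;
    }
  }

  if (want_grad) {
    for (int r = 0; r < p; ++r) {
      const double* col = &X[0] + (size_t)r * n;
      double g = 0.0;
      for (int i = 0; i < m; ++i) {
        double V = 0.0;
        for (int j = cl_start[i]; j < cl_end[i]; ++j) V += w[j] * col[j];
        g += U(r, i) - Ee[i] * V;
      }
      grad[r] = -g;
    }
    grad[p] = -grad[p];
  }
  return List::create(_["nll"] = -loglik, _["grad"] = grad);
}

// O(n) centered moving variance with truncated windows at the edges.
// Window for index t is [t - w/2, t - w/2 + w - 1] clipped to the series,
// i.e. exactly w samples in the interior. Uses cumulative sums of the
// (globally centered) signal for stability.

// [[Rcpp::export]]
NumericVector moving_variance_cpp(NumericVector x, int w) {
  const int n = x.size();
  const int half = w / 2;
  NumericVector out(n);
  double mu = 0.0;
  for (int j = 0; j < n; ++j) mu += x[j];
  mu /= n;
  std::vector<double> c1(n + 1, 0.0), c2(n + 1, 0.0);
  for (int j = 0; j < n; ++j) {
    const double v = x[j] - mu;
    c1[j + 1] = c1[j] + v;
    c2[j + 1] = c2[j] + v * v;
  }
  for (int t = 0; t < n; ++t) {
    int a = t - half; if (a < 0) a = 0;
    int b = t - half + w - 1; if (b > n - 1) b = n - 1;
    const double nn = b - a + 1;
    if (nn < 2) { out[t] = 0.0; continue; }
    const double s1 = c1[b + 1] - c1[a], s2 = c2[b + 1] - c2[a];
    double v = (s2 - s1 * s1 / nn) / (nn - 1.0);
    out[t] = v > 0 ? v : 0.0;
  }
  return out;
}
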