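// Laplace-approximated marginal likelihood for the per-position negative
// binomial mixed model:
//
//   count_{km} ~ NB(mu_{km}, theta),  Var = mu + mu^2/theta
//   log(mu_{km}) = beta[cond(m)] + beta[dev(k,m)] + a_k + offset(m)
//   a_k ~ N(0, sigma^2), one scalar random intercept per barcode
//
// The random intercepts are integrated out barcode-by-barcode with a
// one-dimensional Laplace approximation; the inner mode is found by damped
// Newton (the joint log-likelihood is strictly concave in a_k).
//
// Parameter vector: c(beta_1..beta_p, log_sigma, log_theta).
// Rows must be sorted by barcode; bc_start gives 0-based row offsets per
// barcode (length K+1). cond_idx/dev_idx are 1-based column indices into
// beta; dev_idx == 0 means no deviation column (wild-type rows).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double nb_logpmf(double y, double mu, double theta) {
  // mean/dispersion parameterisation; y >= 0, mu > 0, theta > 0
  double out = R::lgammafn(y + theta) - R::lgammafn(theta) -
               R::lgammafn(y + 1.0) + theta * std::log(theta / (theta + mu));
  if (y > 0.0) out += y * std::log(mu / (theta + mu));
  return out;
}

struct ModelData {
  NumericVector y;
  IntegerVector cond_idx;   // 1-based into beta
  IntegerVector dev_idx;    // 0 = none, else 1-based into beta
  NumericVector offset;
  IntegerVector bc_start;   // length K+1, 0-based
};

static double nll_impl(const NumericVector& par, const ModelData& d) {
  const int p = par.size() - 2;
  const double log_sigma = par[p];
  const double log_theta = par[p + 1];
  const double sig2 = std::exp(2.0 * log_sigma);
  const double theta = std::exp(log_theta);
  const int K = d.bc_start.size() - 1;
  const int n = d.y.size();

  // linear predictor without random effect
  std::vector<double> eta0(n);
  for (int r = 0; r < n; ++r) {
    double e = par[d.cond_idx[r] - 1] + d.offset[r];
    if (d.dev_idx[r] > 0) e += par[d.dev_idx[r] - 1];
    eta0[r] = e;
  }

  double total = 0.0;
  for (int k = 0; k < K; ++k) {
    const int s = d.bc_start[k], e = d.bc_start[k + 1];
    // inner Newton for the conditional mode of a_k
    double a = 0.0;
    for (int it = 0; it < 100; ++it) {
      double g = -a / sig2, h = -1.0 / sig2;
      for (int r = s; r < e; ++r) {
        const double mu = std::exp(eta0[r] + a);
        const double tm = theta + mu;
        g += d.y[r] - (d.y[r] + theta) * mu / tm;
        h -= (d.y[r] + theta) * theta * mu / (tm * tm);
      }
      double step = -g / h;
      if (step > 2.0) step = 2.0;
      if (step < -2.0) step = -2.0;
      a += step;
      if (std::fabs(g) < 1e-10 || std::fabs(step) < 1e-12) break;
    }
    // Laplace contribution
    double ll = -a * a / (2.0 * sig2);
    double W = 0.0;  // -d2/da2 of the data part at the mode
    for (int r = s; r < e; ++r) {
      const double mu = std::exp(eta0[r] + a);
      const double tm = theta + mu;
      ll += nb_logpmf(d.y[r], mu, theta);
      W += (d.y[r] + theta) * theta * mu / (tm * tm);
    }
    ll -= 0.5 * std::log1p(sig2 * W);
    total += ll;
  }
  if (!std::isfinite(total)) return 1e10;
  return -total;
}

static ModelData unpack(NumericVector y, IntegerVector cond_idx,
                        IntegerVector dev_idx, NumericVector offset,
                        IntegerVector bc_start) {
  ModelData d;
  d.y = y; d.cond_idx = cond_idx; d.dev_idx = dev_idx;
  d.offset = offset; d.bc_start = bc_start;
  return d;
}

// [[Rcpp::export]]
double nbml_nll(NumericVector par, NumericVector y, IntegerVector cond_idx,
                IntegerVector dev_idx, NumericVector offset,
                IntegerVector bc_start) {
  return nll_impl(par, unpack(y, cond_idx, dev_idx, offset, bc_start));
}

// Analytic gradient for the fixed effects combined with central
// differences for (log_sigma, log_theta). For barcode k at its Laplace
// mode a_k (where the inner gradient vanishes), with
//   u_m  = y - (y+theta) mu/(theta+mu)          (d ll / d eta)
//   w_m  = (y+theta) theta mu/(theta+mu)^2      (-d2 ll / d eta2)
//   w'_m = w_m (theta-mu)/(theta+mu)            (d w / d eta)
//   W = sum w, D = W + 1/sigma^2, kappa = sigma^2 / (2 (1 + sigma^2 W))
// the envelope theorem gives, for beta column c with row indicators x,
//   d l_k / d beta_c = sum(x u) - kappa (sum(x w') - sum(w') sum(x w)/D)
// (the mode shift enters only through the log-determinant term).
// [[Rcpp::export]]
List nbml_nll_grad(NumericVector par, NumericVector y,
                   IntegerVector cond_idx, IntegerVector dev_idx,
                   NumericVector offset, IntegerVector bc_start) {
  ModelData d = unpack(y, cond_idx, dev_idx, offset, bc_start);
  const int np = par.size();
  const int p = np - 2;
  const double sig2 = std::exp(2.0 * par[p]);
  const double theta = std::exp(par[p + 1]);
  const int K = d.bc_start.size() - 1;
  const int n = d.y.size();

  std::vector<double> eta0(n);
  for (int r = 0; r < n; ++r) {
    double e = par[d.cond_idx[r] - 1] + d.offset[r];
    if (d.dev_idx[r] > 0) e += par[d.dev_idx[r] - 1];
    eta0[r] = e;
  }

  NumericVector grad(np);
  double total = 0.0;
  std::vector<double> su(p), sw(p), swp(p);
  for (int k = 0; k < K; ++k) {
    const int s = d.bc_start[k], e = d.bc_start[k + 1];
    double a = 0.0;
    for (int it = 0; it < 100; ++it) {
      double g = -a / sig2, h = -1.0 / sig2;
      for (int r = s; r < e; ++r) {
        const double mu = std::exp(eta0[r] + a);
        const double tm = theta + mu;
        g += d.y[r] - (d.y[r] + theta) * mu / tm;
        h -= (d.y[r] + theta) * theta * mu / (tm * tm);
      }
      double step = -g / h;
      if (step > 2.0) step = 2.0;
      if (step < -2.0) step = -2.0;
      a += step;
      if (std::fabs(g) < 1e-10 || std::fabs(step) < 1e-12) break;
    }
    double ll = -a * a / (2.0 * sig2);
    double W = 0.0, Wp = 0.0;
    // per-barcode accumulators touch at most 2 columns per row
    std::vector<int> touched;
    for (int r = s; r < e; ++r) {
      const double mu = std::exp(eta0[r] + a);
      const double tm = theta + mu;
      ll += nb_logpmf(d.y[r], mu, theta);
      const double u = d.y[r] - (d.y[r] + theta) * mu / tm;
      const double w = (d.y[r] + theta) * theta * mu / (tm * tm);
      const double wp = w * (theta - mu) / tm;
      W += w; Wp += wp;
      int cols[2] = {d.cond_idx[r] - 1,
                     d.dev_idx[r] > 0 ? d.dev_idx[r] - 1 : -1};
      for (int t = 0; t < 2; ++t) {
        const int c = cols[t];
        if (c < 0) continue;
        if (su[c] == 0.0 && sw[c] == 0.0 && swp[c] == 0.0)
          touched.push_back(c);
        su[c] += u; sw[c] += w; swp[c] += wp;
      }
    }
    ll -= 0.5 * std::log1p(sig2 * W);
    total += ll;
    const double D = W + 1.0 / sig2;
    const double kappa = 0.5 * sig2 / (1.0 + sig2 * W);
    for (size_t t = 0; t < touched.size(); ++t) {
      const int c = touched[t];
      // gradient of the NEGATIVE log-likelihood
      grad[c] -= su[c] - kappa * (swp[c] - Wp * sw[c] / D);
      su[c] = sw[c] = swp[c] = 0.0;
    }
  }
  // variance parameters by central differences
  NumericVector x = clone(par);
  for (int i = p; i < np; ++i) {
    const double h = 1e-6 * (1.0 + std::fabs(par[i]));
    x[i] = par[i] + h;
    const double fp = nll_impl(x, d);
    x[i] = par[i] - h;
    const double fm = nll_impl(x, d);
    x[i] = par[i];
    grad[i] = (fp - fm) / (2.0 * h);
  }
  if (!std::isfinite(total)) total = -1e10;
  return List::create(Named("nll") = -total, Named("grad") = grad);
}

// [[Rcpp::export]]
NumericVector nbml_grad(NumericVector par, NumericVector y,
                        IntegerVector cond_idx, IntegerVector dev_idx,
                        NumericVector offset, IntegerVector bc_start) {
  ModelData d = unpack(y, cond_idx, dev_idx, offset, bc_start);
  const int np = par.size();
  NumericVector g(np);
  NumericVector x = clone(par);
  for (int i = 0; i < np; ++i) {
    const double h = 1e-6 * (1.0 + std::fabs(par[i]));
    x[i] = par[i] + h;
    const double fp = nll_impl(x, d);
    x[i] = par[i] - h;
    const double fm = nll_impl(x, d);
    x[i] = par[i];
    g[i] = (fp - fm) / (2.0 * h);
  }
  return g;
}

// [[Rcpp::export]]
NumericMatrix nbml_hessian(NumericVector par, NumericVector y,
                           IntegerVector cond_idx, IntegerVector dev_idx,
                           NumericVector offset, IntegerVector bc_start) {
  ModelData d = unpack(y, cond_idx, dev_idx, offset, bc_start);
  const int np = par.size();
  NumericMatrix H(np, np);
  NumericVector x = clone(par);
  std::vector<double> h(np);
  for (int i = 0; i < np; ++i) h[i] = 1e-4 * (1.0 + std::fabs(par[i]));
  const double f0 = nll_impl(x, d);
  // diagonal
  for (int i = 0; i < np; ++i) {
    x[i] = par[i] + h[i];
    const double fp = nll_impl(x, d);
    x[i] = par[i] - h[i];
    const double fm = nll_impl(x, d);
    x[i] = par[i];
    H(i, i) = (fp - 2.0 * f0 + fm) / (h[i] * h[i]);
  }
  // off-diagonal
  for (int i = 0; i < np; ++i) {
    for (int j = i + 1; j < np; ++j) {
      x[i] = par[i] + h[i]; x[j] = par[j] + h[j];
      const double fpp = nll_impl(x, d);
      x[j] = par[j] - h[j];
      const double fpm = nll_impl(x, d);
      x[i] = par[i] - h[i]; x[j] = par[j] + h[j];
      const double fmp = nll_impl(x, d);
      x[j] = par[j] - h[j];
      const double fmm = nll_impl(x, d);
      x[i] = par[i]; x[j] = par[j];
      H(i, j) = H(j, i) = (fpp - fpm - fmp + fmm) / (4.0 * h[i] * h[j]);
    }
  }
  return H;
}

// [[Rcpp::export]]
NumericVector nbml_ranef_modes(NumericVector par, NumericVector y,
                               IntegerVector cond_idx, IntegerVector dev_idx,
                               NumericVector offset, IntegerVector bc_start) {
  ModelData d = unpack(y, cond_idx, dev_idx, offset, bc_start);
  const int p = par.size() - 2;
  const double sig2 = std::exp(2.0 * par[p]);
  const double theta = std::exp(par[p + 1]);
  const int K = d.bc_start.size() - 1;
  const int n = d.y.size();
  std::vector<double> eta0(n);
  for (int r = 0; r < n; ++r) {
    double e = par[d.cond_idx[r] - 1] + d.offset[r];
    if (d.dev_idx[r] > 0) e += par[d.dev_idx[r] - 1];
    eta0[r] = e;
  }
  NumericVector modes(K);
  for (int k = 0; k < K; ++k) {
    const int s = d.bc_start[k], e = d.bc_start[k + 1];
    double a = 0.0;
    for (int it = 0; it < 100; ++it) {
      double g = -a / sig2, h = -1.0 / sig2;
      for (int r = s; r < e; ++r) {
        const double mu = std::exp(eta0[r] + a);
        const double tm = theta + mu;
        g += d.y[r] - (d.y[r] + theta) * mu / tm;
        h -= (d.y[r] + theta) * theta * mu / (tm * tm);
      }
      double step = -g / h;
      if (step > 2.0) step = 2.0;
      if (step < -2.0) step = -2.0;
      a += step;
      if (std::fabs(g) < 1e-10 || std::fabs(step) < 1e-12) break;
    }
    modes[k] = a;
  }
  return modes;
}
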