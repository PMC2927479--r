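#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double LOG_SQRT_2PI = 0.9189385332046727417803297;

// Row-wise log of the mixture density, log sum_j w_j f(x_i; mu_j, sigma_j),
// evaluated in log space so that points far in a tail never underflow to
// density zero (which would send the log-likelihood to -Inf).
//
// If resp is non-null it is filled with the responsibilities
// r_ij = w_j f_ij / sum_l w_l f_il (the EM E-step).
static double loglik_core(const NumericVector& x,
                          const NumericVector& w,
                          const NumericVector& mu,
                          const NumericVector& sigma,
                          NumericMatrix* resp) {
  const int n = x.size(), m = w.size();
  std::vector<double> logw(m), logsig(m);
  for (int j = 0; j < m; ++j) {
    logw[j] = std::log(w[j]);
    logsig[j] = std::log(sigma[j]);
  }
  double total = 0.0;
  std::vector<double> lp(m), e(m);
  for (int i = 0; i < n; ++i) {
    double mx = -INFINITY;
    for (int j = 0; j < m; ++j) {
      const double z = (x[i] - mu[j]) / sigma[j];
      lp[j] = logw[j] - logsig[j] - LOG_SQRT_2PI - 0.5 * z * z;
      if (lp[j] > mx) mx = lp[j];
    }
    double s = 0.0;
    for (int j = 0; j < m; ++j) {
      // exponents below -40 contribute < 5e-18 relatively; skipping them
      // avoids slow subnormal exp() calls on far-tail points
      const double d = lp[j] - mx;
      e[j] = (d < -40.0) ? 0.0 : std::exp(d);
      s += e[j];
    }
    total += mx + std::log(s);
    if (resp) {
      for (int j = 0; j < m; ++j) (*resp)(i, j) = e[j] / s;
    }
  }
  return total;
}

// [[Rcpp::export]]
double mix_loglik_cpp(NumericVector x, NumericVector w,
                      NumericVector mu, NumericVector sigma) {
  return loglik_core(x, w, mu, sigma, nullptr);
}

// [[Rcpp::export]]
NumericVector mix_logdensity_cpp(NumericVector x, NumericVector w,
                                 NumericVector mu, NumericVector sigma) {
  const int n = x.size(), m = w.size();
  NumericVector out(n);
  std::vector<double> logw(m), logsig(m), lp(m);
  for (int j = 0; j < m; ++j) {
    logw[j] = std::log(w[j]);
    logsig[j] = std::log(sigma[j]);
  }
  for (int i = 0; i < n; ++i) {
    double mx = -INFINITY;
    for (int j = 0; j < m; ++j) {
      const double z = (x[i] - mu[j]) / sigma[j];
      lp[j] = logw[j] - logsig[j] - LOG_SQRT_2PI - 0.5 * z * z;
      if (lp[j] > mx) mx = lp[j];
    }
    double s = 0.0;
    for (int j = 0; j < m; ++j) s += std::exp(lp[j] - mx);
    out[i] = mx + std::log(s);
  }
  return out;
}

// Full EM iteration loop for a univariate normal mixture.
// Each sweep fuses the E-step and the M-step sufficient statistics into a
// single pass over the data (running sums of r, r*x and r*x^2 per
// component), evaluating the log-likelihood of the *incoming* parameters as
// it goes. Stops when the improvement drops below tol (absolute, nats) or
// after max_iter iterations. Component SDs are floored at sd_floor and
// weights at w_floor to keep the likelihood bounded.
// [[Rcpp::export]]
List mix_em_cpp(NumericVector x, NumericVector w0, NumericVector mu0,
                NumericVector sigma0, double tol, int max_iter,
                double sd_floor, double w_floor) {
  const int n = x.size(), m = w0.size();
  NumericVector w = clone(w0), mu = clone(mu0), sigma = clone(sigma0);
  std::vector<double> logw(m), logsig(m), lp(m), e(m);
  std::vector<double> s0(m), s1(m), s2(m);
  std::vector<double> trace;
  trace.reserve(64);
  bool converged = false;
  bool degenerate = false;
  double ll = -INFINITY;
  int iter = 0;
  for (iter = 0; iter <= max_iter; ++iter) {
    for (int j = 0; j < m; ++j) {
      logw[j] = std::log(w[j]);
      logsig[j] = std::log(sigma[j]);
      s0[j] = s1[j] = s2[j] = 0.0;
    }
    double ll_new = 0.0;
    for (int i = 0; i < n; ++i) {
      double mx = -INFINITY;
      for (int j = 0; j < m; ++j) {
        const double z = (x[i] - mu[j]) / sigma[j];
        lp[j] = logw[j] - logsig[j] - LOG_SQRT_2PI - 0.5 * z * z;
        if (lp[j] > mx) mx = lp[j];
      }
      double s = 0.0;
      for (int j = 0; j < m; ++j) {
        const double d = lp[j] - mx;
        e[j] = (d < -40.0) ? 0.0 : std::exp(d);
        s += e[j];
      }
      ll_new += mx + std::log(s);
      for (int j = 0; j < m; ++j) {
        const double r = e[j] / s;
        s0[j] += r;
        s1[j] += r * x[i];
        s2[j] += r * x[i] * x[i];
      }
    }
    trace.push_back(ll_new);
    // Aitken-accelerated stop: with EM's asymptotically linear convergence,
    // gains shrink geometrically (rate r), so the projected remaining gain is
    // gain / (1 - r); stop when that projection falls below tol.
    bool done = false;
    if (iter > 1) {
      const double gain = ll_new - ll;
      const double prev_gain = ll - trace[trace.size() - 3];
      if (gain < tol && gain >= -1e-8) {
        done = true;
      } else if (gain >= 0 && prev_gain > 0) {
        const double rate = gain / prev_gain;
        if (rate < 1.0 && gain / (1.0 - rate) < tol) done = true;
      }
    }
    ll = ll_new;
    if (done) {
      converged = true;
      break;
    }
    if (iter == max_iter) break;
    // M-step from the accumulated sufficient statistics
    for (int j = 0; j < m; ++j) {
      double nj = s0[j];
      if (nj < n * w_floor) {
        degenerate = true;
        nj = n * w_floor;
      }
      const double nj_m = std::max(s0[j], 1e-300);
      const double mj = s1[j] / nj_m;
      double var = s2[j] / nj_m - mj * mj;
      double sj = (var > 0) ? std::sqrt(var) : 0.0;
      if (sj < sd_floor) {
        sj = sd_floor;
        degenerate = true;
      }
      w[j] = nj / n;
      mu[j] = mj;
      sigma[j] = sj;
    }
    double wsum = 0.0;
    for (int j = 0; j < m; ++j) wsum += w[j];
    for (int j = 0; j < m; ++j) w[j] /= wsum;
  }
  return List::create(_["weight"] = w, _["mean"] = mu, _["sd"] = sigma,
                      _["loglik"] = ll, _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["iterations"] = (int) trace.size() - 1,
                      _["converged"] = converged,
                      _["hit_floor"] = degenerate);
}

// Log-likelihood and its gradient with respect to the unconstrained
// parameterization used by the refinement optimizer:
//   weights  w_j = softmax(a_1..a_{m-1}, 0)
//   sds      sigma_j = exp(ls_j)
// Gradient entries: dL/da_j = sum_i (r_ij - w_j) for j < m,
//                   dL/dmu_j = sum_i r_ij (x_i - mu_j)/sigma_j^2,
//                   dL/dls_j = sum_i r_ij ((x_i - mu_j)^2/sigma_j^2 - 1).
// [[Rcpp::export]]
List mix_loglik_grad_cpp(NumericVector x, NumericVector w,
                         NumericVector mu, NumericVector sigma) {
  const int n = x.size(), m = w.size();
  std::vector<double> logw(m), logsig(m), lp(m), e(m);
  std::vector<double> s_r(m, 0.0), s_mu(m, 0.0), s_ls(m, 0.0);
  for (int j = 0; j < m; ++j) {
    logw[j] = std::log(w[j]);
    logsig[j] = std::log(sigma[j]);
  }
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double mx = -INFINITY;
    for (int j = 0; j < m; ++j) {
      const double z = (x[i] - mu[j]) / sigma[j];
      lp[j] = logw[j] - logsig[j] - LOG_SQRT_2PI - 0.5 * z * z;
      if (lp[j] > mx) mx = lp[j];
    }
    double s = 0.0;
    for (int j = 0; j < m; ++j) {
      const double d = lp[j] - mx;
      e[j] = (d < -40.0) ? 0.0 : std::exp(d);
      s += e[j];
    }
    ll += mx + std::log(s);
    for (int j = 0; j < m; ++j) {
      const double r = e[j] / s;
      const double zd = (x[i] - mu[j]) / sigma[j];
      s_r[j] += r;
      s_mu[j] += r * zd / sigma[j];
      s_ls[j] += r * (zd * zd - 1.0);
    }
  }
  NumericVector ga(std::max(m - 1, 0)), gmu(m), gls(m);
  for (int j = 0; j < m; ++j) {
    if (j < m - 1) ga[j] = s_r[j] - n * w[j];
    gmu[j] = s_mu[j];
    gls[j] = s_ls[j];
  }
  return List::create(_["loglik"] = ll, _["grad_a"] = ga,
                      _["grad_mu"] = gmu, _["grad_logsd"] = gls);
}
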