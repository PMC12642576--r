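#include <Rcpp.h>
using namespace Rcpp;

// Per-cell two-component Poisson mixture EM with offset component means.
// All randomness (restart initial values) is drawn in R; this routine is
// fully deterministic given its arguments.

static inline double pois_log(double x, double mu) {
  // log Poisson pmf with the lgamma(x+1) normalising constant included,
  // so reported log-likelihoods are true log-likelihoods.
  return x * std::log(mu) - mu - std::lgamma(x + 1.0);
}

static inline double comp_mean(double xp, double lambda, bool mult,
                               double floor_) {
  double mu = mult ? xp * lambda : xp + lambda;
  return mu > floor_ ? mu : floor_;
}

// Solve sum_j w_j * (x_j / (xplus_j + lambda) - 1) = 0 on
// [floor, max(x) + 1] by safeguarded Newton; the score is strictly
// decreasing and convex in lambda.
static double solve_lambda_additive(const NumericVector& x,
                                    const NumericVector& xplus,
                                    const NumericVector& w,
                                    double floor_, bool& degenerate) {
  const int g = x.size();
  double sw = 0.0, xmax = 0.0;
  for (int j = 0; j < g; ++j) {
    sw += w[j];
    if (x[j] > xmax) xmax = x[j];
  }
  if (sw <= 1e-12) { degenerate = true; return floor_; }
  degenerate = false;

  double lo = floor_, hi = xmax + 1.0;
  // score at floor
  double f_lo = 0.0;
  for (int j = 0; j < g; ++j) f_lo += w[j] * (x[j] / (xplus[j] + lo) - 1.0);
  if (f_lo <= 0.0) return floor_;

  double lambda = 0.0, sx = 0.0, sxp = 0.0;
  for (int j = 0; j < g; ++j) { sx += w[j] * x[j]; sxp += w[j] * xplus[j]; }
  lambda = sx / sw - sxp / sw; // exact for constant offsets
  if (lambda <= lo) lambda = lo * 2.0 + 1e-8;
  if (lambda >= hi) lambda = 0.5 * (lo + hi);

  for (int it = 0; it < 100; ++it) {
    double f = 0.0, fp = 0.0;
    for (int j = 0; j < g; ++j) {
      double denom = xplus[j] + lambda;
      double t = w[j] * x[j] / denom;
      f += t - w[j];
      fp -= t / denom;
    }
    if (f > 0.0) lo = lambda; else hi = lambda;
    if (std::fabs(f) < 1e-12 * sw) break;
    double step = (fp < 0.0) ? (lambda - f / fp) : std::numeric_limits<double>::quiet_NaN();
    if (!std::isfinite(step) || step <= lo || step >= hi) {
      step = 0.5 * (lo + hi);
    }
    if (std::fabs(step - lambda) < 1e-12 * (1.0 + lambda)) { lambda = step; break; }
    lambda = step;
  }
  return lambda < floor_ ? floor_ : lambda;
}

static double solve_lambda_multiplicative(const NumericVector& x,
                                          const NumericVector& xplus,
                                          const NumericVector& w,
                                          double floor_, bool& degenerate) {
  double sw = 0.0, sx = 0.0, sxp = 0.0;
  for (int j = 0; j < x.size(); ++j) {
    sw += w[j]; sx += w[j] * x[j]; sxp += w[j] * xplus[j];
  }
  if (sw <= 1e-12 || sxp <= 1e-12) { degenerate = true; return floor_; }
  degenerate = false;
  double lambda = sx / sxp;
  return lambda < floor_ ? floor_ : lambda;
}

// [[Rcpp::export]]
List fit_cell_em_cpp(NumericVector x, NumericVector xplus,
                     NumericVector pi0, NumericVector lambda_e0,
                     NumericVector lambda_c0, bool multiplicative,
                     int max_iter, double tol, double lambda_floor,
                     double pi_clamp, bool keep_trace) {
  const int g = x.size();
  const int R = pi0.size();

  NumericVector all_pi(R), all_le(R), all_lc(R), all_ll(R);
  IntegerVector all_iter(R);
  LogicalVector all_conv(R);
  List traces(R);

  NumericVector best_alpha(g);
  double best_ll = R_NegInf;
  int best_r = -1;

  NumericVector alpha(g), le(g), lc(g);

  for (int r = 0; r < R; ++r) {
    double pi = pi0[r], lam_e = lambda_e0[r], lam_c = lambda_c0[r];
    double ll = R_NegInf, ll_old = R_NegInf;
    bool conv = false;
    int iter = 0;
    std::vector<double> tr;

    for (iter = 1; iter <= max_iter; ++iter) {
      // E-step
      double lp = std::log(pi), lq = std::log1p(-pi);
      ll = 0.0;
      for (int j = 0; j < g; ++j) {
        double a = lp + pois_log(x[j], comp_mean(xplus[j], lam_e, multiplicative, lambda_floor));
        double b = lq + pois_log(x[j], comp_mean(xplus[j], lam_c, multiplicative, lambda_floor));
        double m = a > b ? a : b;
        double lse = m + std::log(std::exp(a - m) + std::exp(b - m));
        ll += lse;
        alpha[j] = std::exp(a - lse);
      }
      if (keep_trace) tr.push_back(ll);
      if (std::isfinite(ll_old) &&
          std::fabs(ll - ll_old) < tol * (std::fabs(ll_old) + 1e-12)) {
        conv = true;
        break;
      }
      ll_old = ll;

      // M-step
      double sa = 0.0;
      for (int j = 0; j < g; ++j) sa += alpha[j];
      pi = sa / g;
      if (pi < pi_clamp) pi = pi_clamp;
      if (pi > 1.0 - pi_clamp) pi = 1.0 - pi_clamp;

      NumericVector w1 = alpha;
      NumericVector w0(g);
      for (int j = 0; j < g; ++j) w0[j] = 1.0 - alpha[j];
      bool deg_e = false, deg_c = false;
      if (multiplicative) {
        lam_e = solve_lambda_multiplicative(x, xplus, w1, lambda_floor, deg_e);
        lam_c = solve_lambda_multiplicative(x, xplus, w0, lambda_floor, deg_c);
      } else {
        lam_e = solve_lambda_additive(x, xplus, w1, lambda_floor, deg_e);
        lam_c = solve_lambda_additive(x, xplus, w0, lambda_floor, deg_c);
      }
      if (lam_e < lam_c) {
        std::swap(lam_e, lam_c);
        pi = 1.0 - pi;
        if (pi < pi_clamp) pi = pi_clamp;
        if (pi > 1.0 - pi_clamp) pi = 1.0 - pi_clamp;
        for (int j = 0; j < g; ++j) alpha[j] = 1.0 - alpha[j];
      }
    }
    if (iter > max_iter) iter = max_iter;

    all_pi[r] = pi; all_le[r] = lam_e; all_lc[r] = lam_c;
    all_ll[r] = ll; all_iter[r] = iter; all_conv[r] = conv;
    if (keep_trace) traces[r] = NumericVector(tr.begin(), tr.end());

    if (ll > best_ll) {
      best_ll = ll;
      best_r = r;
      for (int j = 0; j < g; ++j) best_alpha[j] = alpha[j];
    }
  }

  return List::create(
    _["pi"] = all_pi[best_r],
    _["lambda_e"] = all_le[best_r],
    _["lambda_c"] = all_lc[best_r],
    _["loglik"] = best_ll,
    _["n_iter"] = all_iter[best_r],
    _["converged"] = (bool)all_conv[best_r],
    _["restart_index"] = best_r + 1,
    _["alpha"] = best_alpha,
    _["all_pi"] = all_pi,
    _["all_lambda_e"] = all_le,
    _["all_lambda_c"] = all_lc,
    _["all_loglik"] = all_ll,
    _["all_n_iter"] = all_iter,
    _["all_converged"] = all_conv,
    _["traces"] = traces
  );
}
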