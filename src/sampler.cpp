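#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-based RNG (splitmix64 mixing) keyed by (seed, sweep, locus-key).
// Every locus owns an independent stream per sweep, so the chain is
// reproducible across platforms and invariant to marker permutation when the
// locus keys are permuted alongside the markers. Key 0 is reserved for the
// global updates (residual variance, overall mean).
// ---------------------------------------------------------------------------

static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

struct KeyedRng {
  uint64_t base;
  uint64_t ctr;
  KeyedRng(uint64_t seed, uint64_t sweep, uint64_t key) : ctr(0) {
    base = mix64(seed ^ mix64(sweep ^ mix64(key ^ 0xA5A5A5A5DEADBEEFULL)));
  }
  // uniform in (0, 1)
  double unif() {
    uint64_t z = mix64(base ^ (++ctr * 0xD1B54A32D192ED03ULL));
    return ((double)(z >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
  // Marsaglia-Tsang; valid for any a > 0 (boost for a < 1)
  double gamma(double a) {
    if (a < 1.0) {
      double u = unif();
      return gamma(a + 1.0) * std::pow(u, 1.0 / a);
    }
    double d = a - 1.0 / 3.0;
    double c = 1.0 / std::sqrt(9.0 * d);
    for (;;) {
      double x = norm();
      double v = 1.0 + c * x;
      if (v <= 0.0) continue;
      v = v * v * v;
      double u = unif();
      if (std::log(u) < 0.5 * x * x + d - d * v + d * std::log(v))
        return d * v;
    }
  }
  double chisq(double df) { return 2.0 * gamma(df / 2.0); }
};

// log marginal likelihood of the locus-adjusted data under
// y_adj ~ N(0, sigma2 * w w' + sigma2_e I), relative to sigma2 = 0,
// via the rank-one determinant / Sherman-Morrison identities.
static inline double loglik_rel(double sigma2, double wtw, double wy,
                                double sigma2_e) {
  if (sigma2 <= 0.0) return 0.0;
  double a = sigma2 * wtw / sigma2_e;
  return -0.5 * std::log1p(a) +
         0.5 * sigma2 * wy * wy / (sigma2_e * (sigma2_e + sigma2 * wtw));
}

// [[Rcpp::export(name = ".chain_run_cpp")]]
List chain_run_cpp(NumericVector y, NumericMatrix W, std::string method,
                   NumericVector pi, double v_marker, double S_marker,
                   int n_iter, int burn_in, int mh_cycles, int thin,
                   double seed, bool strict_gate, IntegerVector locus_keys,
                   double sigma2_e_init, double sigma2_g_init, double g_init,
                   double mu_init, bool update_resid_var,
                   bool update_marker_var, bool keep_effect_samples) {
  const int n = y.size();
  const int m = W.ncol();
  if (W.nrow() != n) stop("W rows must match length of y");

  const bool bayesA = (method == "bayesA");
  uint64_t useed = (uint64_t)seed;

  std::vector<double> wtw(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    const double* wj = &W(0, j);
    for (int i = 0; i < n; ++i) s += wj[i] * wj[i];
    wtw[j] = s;
  }

  std::vector<double> g(m, g_init), s2g(m, sigma2_g_init);
  double mu = mu_init;
  double sigma2_e = sigma2_e_init;

  // residuals e = y - mu - W g
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) {
    double fit = mu;
    for (int j = 0; j < m; ++j) fit += W(i, j) * g[j];
    e[i] = y[i] - fit;
  }

  // loci are visited in ascending key order, so a permuted marker matrix
  // with permuted keys runs the identical chain (up to the permutation)
  std::vector<int> visit(m);
  for (int j = 0; j < m; ++j) visit[j] = j;
  std::stable_sort(visit.begin(), visit.end(),
                   [&](int a, int b) { return locus_keys[a] < locus_keys[b]; });

  std::vector<double> sum_g(m, 0.0), sum_g2(m, 0.0), sum_in(m, 0.0);
  double sum_mu = 0.0, sum_s2e = 0.0;
  int n_samples = 0;
  std::vector<double> g_samples;

  for (int sweep = 1; sweep <= n_iter; ++sweep) {
    // Step 2 (+5 per locus): marker variances and effects
    for (int jj = 0; jj < m; ++jj) {
      const int j = visit[jj];
      KeyedRng rng(useed, (uint64_t)sweep, (uint64_t)locus_keys[j]);
      const double* wj = &W(0, j);
      double we = 0.0;
      for (int i = 0; i < n; ++i) we += wj[i] * e[i];
      double wy = we + wtw[j] * g[j];  // w_j' y_adj, locus j put back

      double s2_cur = s2g[j];
      if (update_marker_var) {
        if (bayesA) {
          // conjugate draw from x^-2(v + 1, S + g_j^2)
          s2_cur = (S_marker + g[j] * g[j]) / rng.chisq(v_marker + 1.0);
        } else {
          double pj = pi[j];
          double ll_cur = loglik_rel(s2_cur, wtw[j], wy, sigma2_e);
          for (int c = 0; c < mh_cycles; ++c) {
            double alpha = rng.unif();
            double s2_new;
            if (alpha >= 1.0 - pj) {
              if (strict_gate) continue;  // gate closed: skip entirely
              s2_new = 0.0;
            } else {
              s2_new = S_marker / rng.chisq(v_marker);
            }
            double ll_new = loglik_rel(s2_new, wtw[j], wy, sigma2_e);
            if (std::log(rng.unif()) < ll_new - ll_cur) {
              s2_cur = s2_new;
              ll_cur = ll_new;
            }
          }
        }
        s2g[j] = s2_cur;
      }

      // Step 5: effect draw (conjugate normal), or drop locus from model
      double g_new;
      if (s2_cur > 0.0) {
        double denom = wtw[j] + sigma2_e / s2_cur;
        double mean = wy / denom;
        double sd = std::sqrt(sigma2_e / denom);
        g_new = mean + sd * rng.norm();
      } else {
        g_new = 0.0;
      }
      double diff = g[j] - g_new;
      if (diff != 0.0) {
        for (int i = 0; i < n; ++i) e[i] += wj[i] * diff;
        g[j] = g_new;
      }
    }

    KeyedRng rng0(useed, (uint64_t)sweep, 0ULL);
    // Step 3: residual variance from x^-2(n - 2, e'e)
    double ete = 0.0;
    for (int i = 0; i < n; ++i) ete += e[i] * e[i];
    if (update_resid_var) sigma2_e = ete / rng0.chisq((double)(n - 2));

    // Step 4: overall mean
    double sum_e = 0.0;
    for (int i = 0; i < n; ++i) sum_e += e[i];
    double mean_adj = mu + sum_e / n;  // (1'y - 1'Wg)/n
    double mu_new = mean_adj + std::sqrt(sigma2_e / n) * rng0.norm();
    double dmu = mu_new - mu;
    if (dmu != 0.0) {
      for (int i = 0; i < n; ++i) e[i] -= dmu;
      mu = mu_new;
    }

    if (sweep > burn_in && ((sweep - burn_in) % thin == 0)) {
      for (int j = 0; j < m; ++j) {
        sum_g[j] += g[j];
        sum_g2[j] += g[j] * g[j];
        if (s2g[j] > 0.0) sum_in[j] += 1.0;
      }
      sum_mu += mu;
      sum_s2e += sigma2_e;
      ++n_samples;
      if (keep_effect_samples)
        for (int j = 0; j < m; ++j) g_samples.push_back(g[j]);
    }
    if (sweep % 256 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector effect_means(m), effect_vars(m), inclusion(m);
  for (int j = 0; j < m; ++j) {
    effect_means[j] = sum_g[j] / n_samples;
    double v = sum_g2[j] / n_samples - effect_means[j] * effect_means[j];
    effect_vars[j] = v > 0.0 ? v : 0.0;
    inclusion[j] = sum_in[j] / n_samples;
  }
  NumericVector resid(n);
  for (int i = 0; i < n; ++i) resid[i] = e[i];

  List out = List::create(
      _["effect_means"] = effect_means, _["effect_vars"] = effect_vars,
      _["inclusion_freq"] = inclusion, _["mu_mean"] = sum_mu / n_samples,
      _["sigma2_e_mean"] = sum_s2e / n_samples,
      _["n_samples"] = n_samples, _["final_mu"] = mu,
      _["final_sigma2_e"] = sigma2_e, _["final_g"] = NumericVector(g.begin(), g.end()),
      _["final_e"] = resid);
  if (keep_effect_samples) {
    NumericMatrix S((int)(g_samples.size() / m), m);
    int r = 0;
    for (size_t k = 0; k < g_samples.size(); k += m, ++r)
      for (int j = 0; j < m; ++j) S(r, j) = g_samples[k + j];
    out["effect_samples"] = S;
  }
  return out;
}

// [[Rcpp::export(name = ".loglik_rel_cpp")]]
double loglik_rel_export(double sigma2, double wtw, double wy,
                         double sigma2_e) {
  return loglik_rel(sigma2, wtw, wy, sigma2_e);
}

// [[Rcpp::export(name = ".keyed_rng_draws_cpp")]]
NumericVector keyed_rng_draws(double seed, double sweep, double key,
                              int n, std::string what, double df) {
  KeyedRng rng((uint64_t)seed, (uint64_t)sweep, (uint64_t)key);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (what == "unif") out[i] = rng.unif();
    else if (what == "norm") out[i] = rng.norm();
    else if (what == "chisq") out[i] = rng.chisq(df);
    else stop("unknown draw type");
  }
  return out;
}
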