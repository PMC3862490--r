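// Metropolis-within-Gibbs sampler for the hierarchical Poisson model
//   Y_i ~ Poisson(exp(alpha_{t(i)} + omega_{k(i)} + b_{c(i),t(i)}))
// with N(0, alpha_prior_var) year intercepts, N(0, sigma2) observer
// effects, per-year intrinsic CAR fields with conditional variance
// tau2 / n_c, and inverse-gamma(ig_shape, ig_rate) hyperpriors on
// sigma2 and tau2. Random-walk proposals for alpha/omega/b (adaptively
// tuned toward a target acceptance during burn-in only; frozen after),
// conjugate Gibbs draws for sigma2 and tau2, and per-sweep sum-to-zero
// recentering of each year's field (the mean is transferred into
// alpha_t, leaving the likelihood unchanged).
//
// Uses R's RNG throughout, so results are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double rinvgamma(double shape, double rate) {
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// [[Rcpp::export]]
List car_mcmc_cpp(IntegerVector y, IntegerVector yr, IntegerVector obs,
                  IntegerVector cell, int T, int K, int C, List nb,
                  int n_iter, int n_burn, int thin,
                  double alpha_prior_var, double ig_shape, double ig_rate,
                  NumericVector alpha_init, NumericVector omega_init,
                  NumericVector b_init, double sigma2_init, double tau2_init,
                  double target_accept) {
  const int N = y.size();
  if (yr.size() != N || obs.size() != N || cell.size() != N)
    stop("index vectors and counts differ in length");
  if (alpha_init.size() != T || omega_init.size() != K || b_init.size() != C * T)
    stop("initial state dimensions do not match data");

  // record groups
  std::vector<std::vector<int> > recs_t(T), recs_k(K), recs_ct(C * T);
  for (int i = 0; i < N; ++i) {
    if (yr[i] < 0 || yr[i] >= T || obs[i] < 0 || obs[i] >= K ||
        cell[i] < 0 || cell[i] >= C)
      stop("record index out of range");
    recs_t[yr[i]].push_back(i);
    recs_k[obs[i]].push_back(i);
    recs_ct[cell[i] + C * yr[i]].push_back(i);
  }
  // sum of counts per group (sufficient statistic for the shift update)
  std::vector<double> sy_t(T, 0.0), sy_k(K, 0.0), sy_ct(C * T, 0.0);
  for (int i = 0; i < N; ++i) {
    sy_t[yr[i]] += y[i];
    sy_k[obs[i]] += y[i];
    sy_ct[cell[i] + C * yr[i]] += y[i];
  }
  // neighbor structure, 0-based; edge list with c < k for the quadratic form
  std::vector<std::vector<int> > nbr(C);
  std::vector<std::pair<int, int> > edges;
  for (int c = 0; c < C; ++c) {
    IntegerVector v = nb[c];
    if (v.size() == 0) stop("isolated cell in lattice (no neighbors)");
    for (int j = 0; j < v.size(); ++j) {
      int k = v[j] - 1;
      nbr[c].push_back(k);
      if (k > c) edges.push_back(std::make_pair(c, k));
    }
  }

  // state
  std::vector<double> alpha(alpha_init.begin(), alpha_init.end());
  std::vector<double> omega(omega_init.begin(), omega_init.end());
  std::vector<double> b(b_init.begin(), b_init.end());
  double sigma2 = sigma2_init, tau2 = tau2_init;
  // cached Poisson means per record
  std::vector<double> w(N);
  for (int i = 0; i < N; ++i)
    w[i] = std::exp(alpha[yr[i]] + omega[obs[i]] + b[cell[i] + C * yr[i]]);

  // adaptive proposal scales (log sd), per parameter
  std::vector<double> ls_a(T, std::log(0.1)), ls_o(K, std::log(0.1)),
      ls_b(C * T, std::log(0.1));
  std::vector<int> acc_a(T, 0), acc_o(K, 0), acc_b(C * T, 0);
  long keep_acc_a = 0, keep_acc_o = 0, keep_acc_b = 0;
  const int batch = 50;
  int batch_no = 0;

  const int n_keep = (n_iter - n_burn + thin - 1) / thin;
  NumericMatrix out_alpha(n_keep, T), out_omega(n_keep, K), out_b(n_keep, C * T);
  NumericVector out_sigma2(n_keep), out_tau2(n_keep);
  int kept = 0;

  RNGScope scope;
  for (int it = 0; it < n_iter; ++it) {
    // --- year intercepts ---
    for (int t = 0; t < T; ++t) {
      double d = R::rnorm(0.0, std::exp(ls_a[t]));
      double sw = 0.0;
      const std::vector<int>& g = recs_t[t];
      for (size_t j = 0; j < g.size(); ++j) sw += w[g[j]];
      double a0 = alpha[t], a1 = a0 + d;
      double lr = d * sy_t[t] - (std::exp(d) - 1.0) * sw
                  - (a1 * a1 - a0 * a0) / (2.0 * alpha_prior_var);
      if (std::log(R::unif_rand()) < lr) {
        alpha[t] = a1;
        double ed = std::exp(d);
        for (size_t j = 0; j < g.size(); ++j) w[g[j]] *= ed;
        acc_a[t]++; if (it >= n_burn) keep_acc_a++;
      }
    }
    // --- observer effects ---
    for (int k = 0; k < K; ++k) {
      double d = R::rnorm(0.0, std::exp(ls_o[k]));
      double sw = 0.0;
      const std::vector<int>& g = recs_k[k];
      for (size_t j = 0; j < g.size(); ++j) sw += w[g[j]];
      double o0 = omega[k], o1 = o0 + d;
      double lr = d * sy_k[k] - (std::exp(d) - 1.0) * sw
                  - (o1 * o1 - o0 * o0) / (2.0 * sigma2);
      if (std::log(R::unif_rand()) < lr) {
        omega[k] = o1;
        double ed = std::exp(d);
        for (size_t j = 0; j < g.size(); ++j) w[g[j]] *= ed;
        acc_o[k]++; if (it >= n_burn) keep_acc_o++;
      }
    }
    // --- spatial fields, per year ---
    for (int t = 0; t < T; ++t) {
      const int off = C * t;
      for (int c = 0; c < C; ++c) {
        int p = c + off;
        double d = R::rnorm(0.0, std::exp(ls_b[p]));
        double sw = 0.0;
        const std::vector<int>& g = recs_ct[p];
        for (size_t j = 0; j < g.size(); ++j) sw += w[g[j]];
        double nc = (double)nbr[c].size();
        double mbar = 0.0;
        for (size_t j = 0; j < nbr[c].size(); ++j) mbar += b[nbr[c][j] + off];
        mbar /= nc;
        double b0 = b[p], b1 = b0 + d;
        double lr = d * sy_ct[p] - (std::exp(d) - 1.0) * sw
                    - nc * ((b1 - mbar) * (b1 - mbar) - (b0 - mbar) * (b0 - mbar))
                          / (2.0 * tau2);
        if (std::log(R::unif_rand()) < lr) {
          b[p] = b1;
          double ed = std::exp(d);
          for (size_t j = 0; j < g.size(); ++j) w[g[j]] *= ed;
          acc_b[p]++; if (it >= n_burn) keep_acc_b++;
        }
      }
      // sum-to-zero recentering; the level moves into alpha_t so the
      // likelihood (and cached means) are untouched
      double m = 0.0;
      for (int c = 0; c < C; ++c) m += b[c + off];
      m /= C;
      for (int c = 0; c < C; ++c) b[c + off] -= m;
      alpha[t] += m;
    }
    // --- variance components, conjugate Gibbs ---
    double sso = 0.0;
    for (int k = 0; k < K; ++k) sso += omega[k] * omega[k];
    sigma2 = rinvgamma(ig_shape + 0.5 * K, ig_rate + 0.5 * sso);
    double ssb = 0.0;
    for (int t = 0; t < T; ++t) {
      const int off = C * t;
      for (size_t e = 0; e < edges.size(); ++e) {
        double diff = b[edges[e].first + off] - b[edges[e].second + off];
        ssb += diff * diff;
      }
    }
    tau2 = rinvgamma(ig_shape + 0.5 * T * (C - 1.0), ig_rate + 0.5 * ssb);

    // --- proposal adaptation (burn-in only) ---
    if (it < n_burn && (it + 1) % batch == 0) {
      batch_no++;
      double delta = std::min(0.1, 1.0 / std::sqrt((double)batch_no));
      for (int t = 0; t < T; ++t) {
        ls_a[t] += (acc_a[t] > target_accept * batch) ? delta : -delta;
        acc_a[t] = 0;
      }
      for (int k = 0; k < K; ++k) {
        ls_o[k] += (acc_o[k] > target_accept * batch) ? delta : -delta;
        acc_o[k] = 0;
      }
      for (int p = 0; p < C * T; ++p) {
        ls_b[p] += (acc_b[p] > target_accept * batch) ? delta : -delta;
        acc_b[p] = 0;
      }
    }
    // refresh cached means periodically to stop multiplicative drift
    if ((it + 1) % 500 == 0)
      for (int i = 0; i < N; ++i)
        w[i] = std::exp(alpha[yr[i]] + omega[obs[i]] + b[cell[i] + C * yr[i]]);

    // --- store ---
    if (it >= n_burn && (it - n_burn) % thin == 0 && kept < n_keep) {
      for (int t = 0; t < T; ++t) out_alpha(kept, t) = alpha[t];
      for (int k = 0; k < K; ++k) out_omega(kept, k) = omega[k];
      for (int p = 0; p < C * T; ++p) out_b(kept, p) = b[p];
      out_sigma2[kept] = sigma2;
      out_tau2[kept] = tau2;
      kept++;
    }
  }

  double post = std::max(1, n_iter - n_burn);
  return List::create(
      _["alpha"] = out_alpha, _["omega"] = out_omega, _["b"] = out_b,
      _["sigma2"] = out_sigma2, _["tau2"] = out_tau2,
      _["accept"] = NumericVector::create(
          _["alpha"] = keep_acc_a / (post * T),
          _["omega"] = keep_acc_o / (post * K),
          _["b"] = keep_acc_b / (post * C * T)));
}
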