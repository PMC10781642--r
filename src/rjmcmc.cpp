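#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Profile Brownian-motion log-likelihood by Felsenstein pruning.
// Edges must be supplied in postorder; node indices are 0-based with tips
// 0..n-1 and the root at n. Returns the likelihood maximized analytically
// over the root state (GLS mean) and sigma^2.
static double profile_loglik(const IntegerVector& parent,
                             const IntegerVector& child,
                             const NumericVector& len,
                             const NumericVector& scal,
                             const NumericVector& x,
                             int n_tip, int n_node,
                             std::vector<double>& m,
                             std::vector<double>& d,
                             std::vector<double>& W,
                             std::vector<double>& M1,
                             std::vector<double>& M2,
                             std::vector<double>& L,
                             std::vector<int>& done) {
  const int N = n_tip + n_node;
  const int nE = parent.size();
  double Q = 0.0, logV = 0.0;
  for (int k = 0; k < N; ++k) {
    W[k] = 0.0; M1[k] = 0.0; M2[k] = 0.0; L[k] = 0.0; done[k] = 0;
    if (k < n_tip) { m[k] = x[k]; d[k] = 0.0; }
  }
  for (int i = 0; i < nE; ++i) {
    int p = parent[i], c = child[i];
    if (c >= n_tip && !done[c]) {
      m[c] = M1[c] / W[c];
      d[c] = 1.0 / W[c];
      Q += M2[c] - M1[c] * M1[c] / W[c];
      logV += L[c] + std::log(W[c]);
      done[c] = 1;
    }
    double ve = len[i] * scal[i] + d[c];
    double w = 1.0 / ve;
    W[p] += w;
    M1[p] += w * m[c];
    M2[p] += w * m[c] * m[c];
    L[p] += std::log(ve);
  }
  int root = n_tip;
  m[root] = M1[root] / W[root];
  d[root] = 1.0 / W[root];
  Q += M2[root] - M1[root] * M1[root] / W[root];
  logV += L[root] + std::log(W[root]) + std::log(d[root]);
  double n = (double)n_tip;
  double s2 = Q / n;
  if (s2 <= 0.0) return R_PosInf;
  return -0.5 * n * std::log(2.0 * M_PI * s2) - 0.5 * logV - 0.5 * n;
}

// [[Rcpp::export(name = ".bm_profile_loglik_cpp")]]
double bm_profile_loglik_cpp(IntegerVector parent, IntegerVector child,
                             NumericVector len, NumericVector scal,
                             NumericVector x, int n_tip, int n_node) {
  std::vector<double> m(n_tip + n_node), d(n_tip + n_node),
      W(n_tip + n_node), M1(n_tip + n_node), M2(n_tip + n_node),
      L(n_tip + n_node);
  std::vector<int> done(n_tip + n_node);
  return profile_loglik(parent, child, len, scal, x, n_tip, n_node,
                        m, d, W, M1, M2, L, done);
}

// Reversible-jump MCMC over per-branch multiplicative rate scalars of a
// variable-rates Brownian-motion model. The set of scaled branches and their
// scalar values are sampled; unscaled branches have scalar 1. Root state and
// sigma^2 are profiled analytically inside the likelihood. Uses R's RNG, so
// results are reproducible under set.seed().
//
// prior: each branch carries a scalar independently with probability
//        p_scaled (so the number of scaled branches is Binomial(nE,
//        p_scaled), concentrated near homogeneity for small p_scaled);
//        scalar ~ lognormal(0, prior_sdlog).
// moves: update (random-walk on log scalar), birth (draw scalar from the
//        prior), death; standard reversible-jump acceptance ratios (the
//        prior density of the new scalar cancels against the birth proposal).
// [[Rcpp::export(name = ".rjmcmc_vr_cpp")]]
List rjmcmc_vr_cpp(IntegerVector parent, IntegerVector child,
                   NumericVector len, NumericVector x,
                   int n_tip, int n_node,
                   int iterations, double burn_in_fraction,
                   double p_scaled, double prior_sdlog,
                   double step_sdlog, double p_update,
                   int thin) {
  const int nE = parent.size();
  const int N = n_tip + n_node;
  std::vector<double> m(N), d(N), W(N), M1(N), M2(N), L(N);
  std::vector<int> done(N);

  NumericVector scal(nE, 1.0);
  std::vector<int> scaled;          // indices of scaled edges
  std::vector<int> pos(nE, -1);     // position of edge in `scaled`, -1 if not

  double ll = profile_loglik(parent, child, len, scal, x, n_tip, n_node,
                             m, d, W, M1, M2, L, done);
  // prior odds of a branch being scaled vs unscaled
  const double log_prior_odds = std::log(p_scaled) - std::log(1.0 - p_scaled);

  int burn = (int)std::floor(iterations * burn_in_fraction);
  NumericVector mean_scal(nE, 0.0);
  int n_samples = 0;
  int n_keep = (iterations - burn + thin - 1) / thin;
  NumericVector ll_trace(n_keep);
  IntegerVector k_trace(n_keep);
  int kept = 0;
  double acc_update = 0, try_update = 0;
  double acc_birth = 0, try_birth = 0;
  double acc_death = 0, try_death = 0;

  for (int it = 0; it < iterations; ++it) {
    // move type chosen with fixed probabilities so that birth/death proposal
    // probabilities cancel in the acceptance ratio; a move that is not
    // available in the current state (update/death at k = 0, birth at k = nE)
    // is a null transition.
    double u = R::runif(0.0, 1.0);
    int k = scaled.size();
    if (u < p_update && k > 0) {
      // update move
      try_update += 1;
      int j = scaled[(int)(R::runif(0.0, 1.0) * k) % k];
      double old = scal[j];
      double lr_new = std::log(old) + R::rnorm(0.0, step_sdlog);
      double prop = std::exp(lr_new);
      scal[j] = prop;
      double ll_new = profile_loglik(parent, child, len, scal, x,
                                     n_tip, n_node, m, d, W, M1, M2, L, done);
      // lognormal prior ratio times log-scale random-walk Jacobian
      double lp = (std::log(old) * std::log(old) -
                   lr_new * lr_new) / (2.0 * prior_sdlog * prior_sdlog);
      if (std::log(R::runif(0.0, 1.0)) < ll_new - ll + lp) {
        ll = ll_new;
        acc_update += 1;
      } else {
        scal[j] = old;
      }
    } else if (u >= p_update && u < p_update + (1.0 - p_update) / 2.0) {
      // birth move
      if (k < nE) {
        try_birth += 1;
        int n_free = nE - k;
        int which_free = (int)(R::runif(0.0, 1.0) * n_free) % n_free;
        int j = -1, cnt = 0;
        for (int e = 0; e < nE; ++e) {
          if (pos[e] < 0) {
            if (cnt == which_free) { j = e; break; }
            ++cnt;
          }
        }
        double prop = std::exp(R::rnorm(0.0, prior_sdlog));
        scal[j] = prop;
        double ll_new = profile_loglik(parent, child, len, scal, x,
                                       n_tip, n_node, m, d, W, M1, M2, L, done);
        // prior ratio on k, proposal ratio: scalar prior cancels;
        // q(death chooses j) = 1/(k+1); q(birth chooses j) = 1/n_free
        double lacc = ll_new - ll + log_prior_odds +
          std::log((double)n_free) - std::log((double)(k + 1));
        if (std::log(R::runif(0.0, 1.0)) < lacc) {
          ll = ll_new;
          pos[j] = scaled.size();
          scaled.push_back(j);
          acc_birth += 1;
        } else {
          scal[j] = 1.0;
        }
      }
    } else if (u >= p_update) {
      // death move
      if (k > 0) {
        try_death += 1;
        int idx = (int)(R::runif(0.0, 1.0) * k) % k;
        int j = scaled[idx];
        double old = scal[j];
        scal[j] = 1.0;
        double ll_new = profile_loglik(parent, child, len, scal, x,
                                       n_tip, n_node, m, d, W, M1, M2, L, done);
        int n_free_after = nE - k + 1;
        double lacc = ll_new - ll - log_prior_odds +
          std::log((double)k) - std::log((double)n_free_after);
        if (std::log(R::runif(0.0, 1.0)) < lacc) {
          ll = ll_new;
          int last = scaled.size() - 1;
          scaled[idx] = scaled[last];
          pos[scaled[idx]] = idx;
          scaled.pop_back();
          pos[j] = -1;
          acc_death += 1;
        } else {
          scal[j] = old;
        }
      }
    }
    if (it >= burn) {
      for (int e = 0; e < nE; ++e) mean_scal[e] += scal[e];
      ++n_samples;
      if ((it - burn) % thin == 0 && kept < n_keep) {
        ll_trace[kept] = ll;
        k_trace[kept] = (int)scaled.size();
        ++kept;
      }
    }
  }
  for (int e = 0; e < nE; ++e) mean_scal[e] /= (double)n_samples;

  return List::create(
    _["mean_scalar"] = mean_scal,
    _["loglik_trace"] = ll_trace[Rcpp::Range(0, kept - 1)],
    _["k_trace"] = k_trace[Rcpp::Range(0, kept - 1)],
    _["acceptance"] = NumericVector::create(
      _["update"] = try_update > 0 ? acc_update / try_update : NA_REAL,
      _["birth"] = try_birth > 0 ? acc_birth / try_birth : NA_REAL,
      _["death"] = try_death > 0 ? acc_death / try_death : NA_REAL),
    _["n_samples"] = n_samples
  );
}
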