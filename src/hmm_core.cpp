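// Forward recursion, filtering probabilities and Viterbi decoding for
// hidden Markov models with per-step (covariate-dependent) transition
// matrices. All computations are in log space with log-sum-exp scaling.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double logsumexp(const arma::rowvec& v) {
  double m = v.max();
  if (!std::isfinite(m)) return m;
  return m + std::log(arma::accu(arma::exp(v - m)));
}

// logobs: n x k matrix of per-step log observation densities
// logtrans: k x k x n cube (slice t moves step t-1 -> t; slice 0 unused)
//   or a k x k x 1 cube for covariate-free homogeneous transitions
// logdelta: length-k initial log distribution
// [[Rcpp::export]]
List hmm_forward_cpp(const arma::mat& logobs, const arma::cube& logtrans,
                     const arma::rowvec& logdelta) {
  const int n = logobs.n_rows, k = logobs.n_cols;
  const bool homo = (logtrans.n_slices == 1);
  arma::mat logalpha(n, k);
  logalpha.row(0) = logdelta + logobs.row(0);
  arma::rowvec work(k);
  for (int t = 1; t < n; ++t) {
    const int s = homo ? 0 : t;
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i)
        work(i) = logalpha(t - 1, i) + logtrans(i, j, s);
      logalpha(t, j) = logsumexp(work) + logobs(t, j);
    }
  }
  double ll = logsumexp(logalpha.row(n - 1));
  return List::create(_["loglik"] = ll, _["logalpha"] = logalpha);
}

// Most probable joint path; ties broken toward the lower state index.
// Returns 1-based state indices.
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(const arma::mat& logobs, const arma::cube& logtrans,
                              const arma::rowvec& logdelta) {
  const int n = logobs.n_rows, k = logobs.n_cols;
  const bool homo = (logtrans.n_slices == 1);
  arma::mat score(n, k);
  arma::imat back(n, k);
  score.row(0) = logdelta + logobs.row(0);
  for (int t = 1; t < n; ++t) {
    const int s = homo ? 0 : t;
    for (int j = 0; j < k; ++j) {
      double best = -arma::datum::inf;
      int arg = 0;
      for (int i = 0; i < k; ++i) {
        double cand = score(t - 1, i) + logtrans(i, j, s);
        if (cand > best) { best = cand; arg = i; }  // strict > keeps lowest i
      }
      score(t, j) = best + logobs(t, j);
      back(t, j) = arg;
    }
  }
  IntegerVector path(n);
  int arg = 0;
  double best = -arma::datum::inf;
  for (int j = 0; j < k; ++j)
    if (score(n - 1, j) > best) { best = score(n - 1, j); arg = j; }
  path[n - 1] = arg + 1;
  for (int t = n - 1; t > 0; --t) {
    arg = back(t, arg);
    path[t - 1] = arg + 1;
  }
  return path;
}
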