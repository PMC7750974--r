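#include <Rcpp.h>
using namespace Rcpp;

// Log-domain HMM machinery for the three-state (P/N/U) genome segmentation.
// Emissions are fixed bin-specific log-probabilities; only the transition
// matrix and initial distribution are re-estimated (Baum-Welch restricted
// to transitions). Everything runs in log space: chains span 1e4-1e6 bins
// and probability products underflow otherwise.

static inline double logsumexp3(const double *x, int K) {
  double m = x[0];
  for (int k = 1; k < K; ++k) if (x[k] > m) m = x[k];
  if (!R_finite(m)) return m;
  double s = 0.0;
  for (int k = 0; k < K; ++k) s += std::exp(x[k] - m);
  return m + std::log(s);
}

// Forward-backward for one chain. logE is L x K. Accumulates expected
// transition counts (xi, normal domain) and the state posterior at t = 0
// (gamma0) into the supplied buffers; returns the chain log-likelihood.
static double fb_chain(const NumericMatrix &logE,
                       const NumericMatrix &logA,
                       const NumericVector &logPi,
                       NumericMatrix &xi_acc,
                       NumericVector &gamma0_acc) {
  const int L = logE.nrow(), K = logE.ncol();
  NumericMatrix la(L, K), lb(L, K);
  std::vector<double> buf(K);

  for (int k = 0; k < K; ++k) la(0, k) = logPi[k] + logE(0, k);
  for (int t = 1; t < L; ++t) {
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j) buf[j] = la(t - 1, j) + logA(j, k);
      la(t, k) = logsumexp3(buf.data(), K) + logE(t, k);
    }
  }
  std::vector<double> last(K);
  for (int k = 0; k < K; ++k) last[k] = la(L - 1, k);
  const double ll = logsumexp3(last.data(), K);

  for (int k = 0; k < K; ++k) lb(L - 1, k) = 0.0;
  for (int t = L - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      for (int k = 0; k < K; ++k) buf[k] = logA(j, k) + logE(t + 1, k) + lb(t + 1, k);
      lb(t, j) = logsumexp3(buf.data(), K);
    }
  }

  for (int t = 0; t + 1 < L; ++t)
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi_acc(j, k) += std::exp(la(t, j) + logA(j, k) + logE(t + 1, k) +
                                 lb(t + 1, k) - ll);
  for (int k = 0; k < K; ++k)
    gamma0_acc[k] += std::exp(la(0, k) + lb(0, k) - ll);
  return ll;
}

// [[Rcpp::export(name = ".em_fit_cpp")]]
List em_fit_cpp(List logE_chains, NumericMatrix A0, NumericVector pi0,
                double tol, int max_iter, bool update_initial) {
  const int K = A0.ncol();
  NumericMatrix A = clone(A0);
  NumericVector pi = clone(pi0);
  std::vector<double> ll_hist, delta_hist;
  bool converged = false;
  long n_trans = 0;
  for (R_xlen_t c = 0; c < logE_chains.size(); ++c) {
    NumericMatrix e = logE_chains[c];
    n_trans += e.nrow() - 1;
  }

  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    NumericMatrix logA(K, K);
    NumericVector logPi(K);
    for (int j = 0; j < K; ++j) {
      logPi[j] = std::log(pi[j]);
      for (int k = 0; k < K; ++k) logA(j, k) = std::log(A(j, k));
    }
    NumericMatrix xi(K, K);
    NumericVector g0(K);
    double ll = 0.0;
    for (R_xlen_t c = 0; c < logE_chains.size(); ++c) {
      NumericMatrix e = logE_chains[c];
      ll += fb_chain(e, logA, logPi, xi, g0);
    }
    ll_hist.push_back(ll);

    if (n_trans == 0) { delta_hist.push_back(0.0); converged = true; ++it; break; }

    NumericMatrix Anew(K, K);
    double delta = 0.0;
    for (int j = 0; j < K; ++j) {
      double rs = 0.0;
      for (int k = 0; k < K; ++k) rs += xi(j, k);
      for (int k = 0; k < K; ++k) {
        // a state never visited keeps its previous row (no evidence)
        Anew(j, k) = (rs > 0.0) ? xi(j, k) / rs : A(j, k);
        double d = std::fabs(Anew(j, k) - A(j, k));
        if (d > delta) delta = d;
      }
    }
    A = Anew;
    if (update_initial) {
      double gs = 0.0;
      for (int k = 0; k < K; ++k) gs += g0[k];
      if (gs > 0.0) for (int k = 0; k < K; ++k) pi[k] = g0[k] / gs;
    }
    delta_hist.push_back(delta);
    if (delta < tol) { converged = true; ++it; break; }
  }

  return List::create(_["transition"] = A, _["initial"] = pi,
                      _["loglik"] = wrap(ll_hist), _["delta"] = wrap(delta_hist),
                      _["n_iter"] = (int)ll_hist.size(),
                      _["converged"] = converged);
}

// [[Rcpp::export(name = ".viterbi_cpp")]]
IntegerVector viterbi_cpp(NumericMatrix logE, NumericMatrix logA,
                          NumericVector logPi) {
  const int L = logE.nrow(), K = logE.ncol();
  IntegerVector path(L);
  if (L == 0) return path;
  NumericMatrix v(L, K);
  IntegerMatrix bp(L, K);
  for (int k = 0; k < K; ++k) v(0, k) = logPi[k] + logE(0, k);
  for (int t = 1; t < L; ++t) {
    for (int k = 0; k < K; ++k) {
      int best = 0;
      double bv = v(t - 1, 0) + logA(0, k);
      for (int j = 1; j < K; ++j) {
        double cand = v(t - 1, j) + logA(j, k);
        if (cand > bv) { bv = cand; best = j; }  // strict >: ties go to lowest state index
      }
      v(t, k) = bv + logE(t, k);
      bp(t, k) = best;
    }
  }
  int best = 0;
  double bv = v(L - 1, 0);
  for (int k = 1; k < K; ++k) if (v(L - 1, k) > bv) { bv = v(L - 1, k); best = k; }
  path[L - 1] = best + 1;  // 1-based state index for R
  for (int t = L - 1; t > 0; --t) {
    best = bp(t, best);
    path[t - 1] = best + 1;
  }
  return path;
}

// [[Rcpp::export(name = ".path_loglik_cpp")]]
double path_loglik_cpp(NumericMatrix logE, NumericMatrix logA,
                       NumericVector logPi, IntegerVector path) {
  const int L = logE.nrow();
  if (L == 0) return 0.0;
  double ll = logPi[path[0] - 1] + logE(0, path[0] - 1);
  for (int t = 1; t < L; ++t)
    ll += logA(path[t - 1] - 1, path[t] - 1) + logE(t, path[t] - 1);
  return ll;
}
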