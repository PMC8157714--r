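#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward and Viterbi for a Gaussian-emission HMM with
// isotropic 3-D emissions (one mean vector and one sd per state).

static void emission_dens(const NumericMatrix& X, const NumericMatrix& mu,
                          const NumericVector& sd, std::vector<double>& B,
                          int T, int K) {
  // B[t*K + k]: density rescaled per-frame outside; store log then exponentiate
  std::vector<double> lc(K);
  for (int k = 0; k < K; ++k)
    lc[k] = -1.5 * std::log(2.0 * M_PI * sd[k] * sd[k]);
  for (int t = 0; t < T; ++t) {
    double m = -INFINITY;
    for (int k = 0; k < K; ++k) {
      double r2 = 0.0;
      for (int a = 0; a < 3; ++a) {
        double d = X(t, a) - mu(k, a);
        r2 += d * d;
      }
      double lp = lc[k] - 0.5 * r2 / (sd[k] * sd[k]);
      B[(size_t)t * K + k] = lp;
      if (lp > m) m = lp;
    }
    for (int k = 0; k < K; ++k)
      B[(size_t)t * K + k] = std::exp(B[(size_t)t * K + k] - m) + 1e-300;
  }
}

// [[Rcpp::export]]
List hmm_estep_cpp(NumericMatrix X, NumericMatrix mu, NumericVector sd,
                   NumericVector pi0, NumericMatrix A) {
  const int T = X.nrow(), K = mu.nrow();
  std::vector<double> B((size_t)T * K);
  emission_dens(X, mu, sd, B, T, K);

  std::vector<double> alpha((size_t)T * K), beta((size_t)T * K), csc(T);
  // forward
  double c = 0.0;
  for (int k = 0; k < K; ++k) { alpha[k] = pi0[k] * B[k]; c += alpha[k]; }
  csc[0] = c;
  for (int k = 0; k < K; ++k) alpha[k] /= c;
  double loglik = std::log(c);
  for (int t = 1; t < T; ++t) {
    c = 0.0;
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += alpha[(size_t)(t - 1) * K + j] * A(j, k);
      double v = s * B[(size_t)t * K + k];
      alpha[(size_t)t * K + k] = v;
      c += v;
    }
    csc[t] = c;
    for (int k = 0; k < K; ++k) alpha[(size_t)t * K + k] /= c;
    loglik += std::log(c);
  }
  // note: per-frame max subtraction in emission_dens cancels in gamma/xi but
  // shifts loglik; recompute exact loglik below by adding the shifts back.
  // To keep it exact we instead recompute densities without shift for loglik:
  {
    std::vector<double> lc(K);
    for (int k = 0; k < K; ++k)
      lc[k] = -1.5 * std::log(2.0 * M_PI * sd[k] * sd[k]);
    double extra = 0.0;
    for (int t = 0; t < T; ++t) {
      double m = -INFINITY;
      for (int k = 0; k < K; ++k) {
        double r2 = 0.0;
        for (int a = 0; a < 3; ++a) {
          double d = X(t, a) - mu(k, a);
          r2 += d * d;
        }
        double lp = lc[k] - 0.5 * r2 / (sd[k] * sd[k]);
        if (lp > m) m = lp;
      }
      extra += m;
    }
    loglik += extra;
  }
  // backward
  for (int k = 0; k < K; ++k) beta[(size_t)(T - 1) * K + k] = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int k = 0; k < K; ++k)
        s += A(j, k) * B[(size_t)(t + 1) * K + k] * beta[(size_t)(t + 1) * K + k];
      beta[(size_t)t * K + j] = s / csc[t + 1];
    }
  }
  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      double v = alpha[(size_t)t * K + k] * beta[(size_t)t * K + k];
      gamma(t, k) = v;
      s += v;
    }
    for (int k = 0; k < K; ++k) gamma(t, k) /= s;
  }
  NumericMatrix xisum(K, K);
  for (int t = 0; t < T - 1; ++t) {
    double s = 0.0;
    std::vector<double> tmp((size_t)K * K);
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k) {
        double v = alpha[(size_t)t * K + j] * A(j, k) *
                   B[(size_t)(t + 1) * K + k] * beta[(size_t)(t + 1) * K + k];
        tmp[(size_t)j * K + k] = v;
        s += v;
      }
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k) xisum(j, k) += tmp[(size_t)j * K + k] / s;
  }
  return List::create(_["loglik"] = loglik, _["gamma"] = gamma, _["xisum"] = xisum);
}

// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericMatrix X, NumericMatrix mu, NumericVector sd,
                              NumericVector pi0, NumericMatrix A) {
  const int T = X.nrow(), K = mu.nrow();
  std::vector<double> lB((size_t)T * K), lc(K);
  for (int k = 0; k < K; ++k)
    lc[k] = -1.5 * std::log(2.0 * M_PI * sd[k] * sd[k]);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double r2 = 0.0;
      for (int a = 0; a < 3; ++a) {
        double d = X(t, a) - mu(k, a);
        r2 += d * d;
      }
      lB[(size_t)t * K + k] = lc[k] - 0.5 * r2 / (sd[k] * sd[k]);
    }
  std::vector<double> delta((size_t)T * K);
  std::vector<int> psi((size_t)T * K);
  for (int k = 0; k < K; ++k)
    delta[k] = std::log(pi0[k] + 1e-300) + lB[k];
  std::vector<double> lA((size_t)K * K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k) lA[(size_t)j * K + k] = std::log(A(j, k) + 1e-300);
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double best = -INFINITY; int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta[(size_t)(t - 1) * K + j] + lA[(size_t)j * K + k];
        if (v > best) { best = v; arg = j; }
      }
      delta[(size_t)t * K + k] = best + lB[(size_t)t * K + k];
      psi[(size_t)t * K + k] = arg;
    }
  IntegerVector path(T);
  {
    double best = -INFINITY; int arg = 0;
    for (int k = 0; k < K; ++k)
      if (delta[(size_t)(T - 1) * K + k] > best) { best = delta[(size_t)(T - 1) * K + k]; arg = k; }
    path[T - 1] = arg;
  }
  for (int t = T - 2; t >= 0; --t)
    path[t] = psi[(size_t)(t + 1) * K + path[t + 1]];
  for (int t = 0; t < T; ++t) path[t] += 1;   // 1-based states for R
  return path;
}

// Simulate a state chain + isotropic Gaussian emissions from fitted HMM
// parameters (parametric bootstrap).  Uses the R RNG.
// [[Rcpp::export]]
List hmm_simulate_cpp(int T, NumericVector pi0, NumericMatrix A,
                      NumericMatrix mu, NumericVector sd) {
  const int K = pi0.size();
  IntegerVector states(T);
  NumericMatrix X(T, 3);
  int s = 0;
  {
    double u = unif_rand(), acc = 0.0;
    for (int k = 0; k < K; ++k) { acc += pi0[k]; if (u <= acc) { s = k; break; } s = k; }
  }
  for (int t = 0; t < T; ++t) {
    if (t > 0) {
      double u = unif_rand(), acc = 0.0;
      int ns = s;
      for (int k = 0; k < K; ++k) { acc += A(s, k); if (u <= acc) { ns = k; break; } ns = k; }
      s = ns;
    }
    states[t] = s + 1;
    for (int a = 0; a < 3; ++a) X(t, a) = mu(s, a) + sd[s] * norm_rand();
  }
  return List::create(_["states"] = states, _["X"] = X);
}
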