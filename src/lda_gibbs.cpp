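#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Collapsed Gibbs sampler for symmetric-prior LDA.
//
// docs: list of 1-based integer word-id vectors; K topics; V vocabulary
// size. Posterior means of the topic-word (beta) and doc-topic (theta)
// distributions are averaged over post-burn-in thinned sweeps. Uses R's
// RNG (unif_rand), so results are a pure function of the R-side seed.
//
// [[Rcpp::export]]
List lda_gibbs_cpp(List docs, int K, double alpha, double eta, int V,
                   int n_iter, int burn_in, int thin) {
  const int D = docs.size();
  std::vector<std::vector<int> > w(D), z(D);
  long total_tokens = 0;
  for (int d = 0; d < D; ++d) {
    IntegerVector dd = docs[d];
    w[d].resize(dd.size());
    z[d].resize(dd.size());
    for (int i = 0; i < dd.size(); ++i) {
      if (dd[i] < 1 || dd[i] > V) stop("word id out of range");
      w[d][i] = dd[i] - 1;
    }
    total_tokens += dd.size();
  }

  std::vector<long> nwk((size_t)K * V, 0), ndk((size_t)D * K, 0), nk(K, 0);
  for (int d = 0; d < D; ++d) {
    for (size_t i = 0; i < w[d].size(); ++i) {
      int k = (int)(unif_rand() * K);
      if (k == K) k = K - 1;
      z[d][i] = k;
      ++nwk[(size_t)k * V + w[d][i]];
      ++ndk[(size_t)d * K + k];
      ++nk[k];
    }
  }

  NumericMatrix beta_acc(K, V), theta_acc(D, K);
  NumericVector loglik(n_iter);
  std::vector<double> pr(K);
  int n_samples = 0;
  const double Veta = V * eta;

  for (int iter = 0; iter < n_iter; ++iter) {
    for (int d = 0; d < D; ++d) {
      long *ndk_d = &ndk[(size_t)d * K];
      for (size_t i = 0; i < w[d].size(); ++i) {
        const int wi = w[d][i];
        const int zi = z[d][i];
        --nwk[(size_t)zi * V + wi]; --ndk_d[zi]; --nk[zi];
        double s = 0.0;
        for (int k = 0; k < K; ++k) {
          pr[k] = (ndk_d[k] + alpha) * (nwk[(size_t)k * V + wi] + eta) /
                  (nk[k] + Veta);
          s += pr[k];
        }
        double u = unif_rand() * s;
        int k = 0;
        double acc = pr[0];
        while (u > acc && k < K - 1) acc += pr[++k];
        z[d][i] = k;
        ++nwk[(size_t)k * V + wi]; ++ndk_d[k]; ++nk[k];
      }
    }

    // collapsed joint log P(w, z) up to constants: Dirichlet-multinomial
    // over topic-word counts plus doc-topic counts (monitoring only)
    double ll = 0.0;
    for (int k = 0; k < K; ++k) {
      for (int v = 0; v < V; ++v)
        if (nwk[(size_t)k * V + v] > 0)
          ll += R::lgammafn(nwk[(size_t)k * V + v] + eta) - R::lgammafn(eta);
      ll -= R::lgammafn(nk[k] + Veta);
    }
    for (int d = 0; d < D; ++d)
      for (int k = 0; k < K; ++k)
        if (ndk[(size_t)d * K + k] > 0)
          ll += R::lgammafn(ndk[(size_t)d * K + k] + alpha) - R::lgammafn(alpha);
    loglik[iter] = ll;

    if (iter >= burn_in && (iter - burn_in) % thin == 0) {
      for (int k = 0; k < K; ++k) {
        const double denom = nk[k] + Veta;
        for (int v = 0; v < V; ++v)
          beta_acc(k, v) += (nwk[(size_t)k * V + v] + eta) / denom;
      }
      for (int d = 0; d < D; ++d) {
        const double denom = (double)w[d].size() + K * alpha;
        for (int k = 0; k < K; ++k)
          theta_acc(d, k) += (ndk[(size_t)d * K + k] + alpha) / denom;
      }
      ++n_samples;
    }
  }

  long count_sum = 0;
  for (int k = 0; k < K; ++k) count_sum += nk[k];
  if (count_sum != total_tokens) stop("Gibbs count conservation violated");

  if (n_samples == 0) stop("no post-burn-in samples: check n_iter/burn_in/thin");
  for (int k = 0; k < K; ++k)
    for (int v = 0; v < V; ++v) beta_acc(k, v) /= n_samples;
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < K; ++k) theta_acc(d, k) /= n_samples;

  return List::create(_["beta_hat"] = beta_acc, _["theta_hat"] = theta_acc,
                      _["loglik"] = loglik, _["n_samples"] = n_samples,
                      _["total_tokens"] = (double)total_tokens);
}
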