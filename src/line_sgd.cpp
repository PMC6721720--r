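// Second-order LINE training loop: stochastic gradient descent over
// directed weighted edges with negative sampling, alias-method draws and a
// self-contained deterministic RNG (single-threaded, bitwise reproducible
// for a fixed seed).
#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct AliasTable {
  std::vector<double> prob;
  std::vector<int> alias;

  explicit AliasTable(const std::vector<double>& w) {
    const int n = static_cast<int>(w.size());
    prob.assign(n, 0.0);
    alias.assign(n, 0);
    double total = 0.0;
    for (double x : w) total += x;
    std::vector<double> scaled(n);
    std::vector<int> small, large;
    for (int i = 0; i < n; ++i) {
      scaled[i] = w[i] * n / total;
      (scaled[i] < 1.0 ? small : large).push_back(i);
    }
    while (!small.empty() && !large.empty()) {
      int s = small.back(); small.pop_back();
      int l = large.back(); large.pop_back();
      prob[s] = scaled[s];
      alias[s] = l;
      scaled[l] = scaled[l] + scaled[s] - 1.0;
      (scaled[l] < 1.0 ? small : large).push_back(l);
    }
    for (int s : small) prob[s] = 1.0;
    for (int l : large) prob[l] = 1.0;
  }

  int draw(std::mt19937_64& rng, std::uniform_real_distribution<double>& unif) const {
    const int n = static_cast<int>(prob.size());
    int i = static_cast<int>(unif(rng) * n);
    if (i >= n) i = n - 1;
    return unif(rng) < prob[i] ? i : alias[i];
  }
};

inline double sigmoid(double x) {
  if (x > 10.0) return 1.0;
  if (x < -10.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

} // namespace

// [[Rcpp::export]]
List line_sgd_cpp(IntegerVector src, IntegerVector dst, NumericVector weight,
                  int n_nodes, int dim, int negatives, double total_samples,
                  double rho0, int seed) {
  const int m = src.size();
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // Vertex vectors start small-uniform, context vectors at zero.
  std::vector<double> U(static_cast<size_t>(n_nodes) * dim);
  std::vector<double> C(static_cast<size_t>(n_nodes) * dim, 0.0);
  const double half = 0.5 / dim;
  for (double& u : U) u = (unif(rng) * 2.0 - 1.0) * half;

  // Edge sampling proportional to weight; negative ("noise") node sampling
  // proportional to weighted out-degree ^ 0.75.
  std::vector<double> w(weight.begin(), weight.end());
  AliasTable edge_alias(w);
  std::vector<double> deg(n_nodes, 0.0);
  for (int e = 0; e < m; ++e) deg[src[e]] += weight[e];
  std::vector<double> noise(n_nodes);
  for (int i = 0; i < n_nodes; ++i) noise[i] = std::pow(deg[i], 0.75);
  AliasTable noise_alias(noise);

  std::vector<double> err(dim);
  const long long total = static_cast<long long>(total_samples);
  for (long long s = 0; s < total; ++s) {
    double rho = rho0 * (1.0 - static_cast<double>(s) / total);
    if (rho < rho0 * 1e-4) rho = rho0 * 1e-4;
    const int e = edge_alias.draw(rng, unif);
    const int i = src[e];
    const int j = dst[e];
    double* ui = &U[static_cast<size_t>(i) * dim];
    std::fill(err.begin(), err.end(), 0.0);
    for (int t = 0; t < negatives + 1; ++t) {
      int target;
      double label;
      if (t == 0) {
        target = j;
        label = 1.0;
      } else {
        target = noise_alias.draw(rng, unif);
        if (target == j) continue;
        label = 0.0;
      }
      double* ct = &C[static_cast<size_t>(target) * dim];
      double f = 0.0;
      for (int d = 0; d < dim; ++d) f += ui[d] * ct[d];
      const double g = (label - sigmoid(f)) * rho;
      for (int d = 0; d < dim; ++d) {
        err[d] += g * ct[d];
        ct[d] += g * ui[d];
      }
    }
    for (int d = 0; d < dim; ++d) ui[d] += err[d];
  }

  NumericMatrix Um(n_nodes, dim), Cm(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i)
    for (int d = 0; d < dim; ++d) {
      Um(i, d) = U[static_cast<size_t>(i) * dim + d];
      Cm(i, d) = C[static_cast<size_t>(i) * dim + d];
    }
  return List::create(_["vertex"] = Um, _["context"] = Cm);
}
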