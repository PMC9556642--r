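// Within-block label-permutation null for the replicated-block Friedman
// statistic. Ranks are jointly assigned within each block once; under the
// null the condition labels are exchangeable within block, so the
// permutation distribution of the statistic follows from shuffling each
// block's rank vector. Self-contained xorshift RNG keeps the p-value
// deterministic and independent of R's RNG state.
#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline uint64_t xorshift64(uint64_t &st) {
  st ^= st << 13;
  st ^= st >> 7;
  st ^= st << 17;
  return st;
}

// [[Rcpp::export(name = ".perm_friedman_cpp")]]
double perm_friedman_cpp(NumericMatrix ranks, int m, int k, double V,
                         double obs, int n_perm, double seed) {
  int nb = ranks.nrow();
  int N = m * k;
  if (ranks.ncol() != N) stop("rank matrix must be blocks x (m*k)");
  double E = nb * m * (N + 1) / 2.0;
  uint64_t st = (uint64_t)seed * 2654435761u + 88172645463325252ull;
  for (int w = 0; w < 16; ++w) xorshift64(st);
  std::vector<std::vector<double>> rk(nb, std::vector<double>(N));
  for (int i = 0; i < nb; ++i)
    for (int j = 0; j < N; ++j) rk[i][j] = ranks(i, j);
  std::vector<double> S(k);
  int count = 0;
  for (int b = 0; b < n_perm; ++b) {
    std::fill(S.begin(), S.end(), 0.0);
    for (int i = 0; i < nb; ++i) {
      std::vector<double> &r = rk[i];
      for (int j = N - 1; j > 0; --j) {            // Fisher-Yates
        int u = (int)(xorshift64(st) % (uint64_t)(j + 1));
        std::swap(r[j], r[u]);
      }
      for (int j = 0; j < k; ++j)
        for (int q = 0; q < m; ++q) S[j] += r[j * m + q];
    }
    double chi = 0.0;
    for (int j = 0; j < k; ++j) chi += (S[j] - E) * (S[j] - E);
    chi *= (double)(k - 1) / ((double)k * V);
    if (chi >= obs - 1e-12) ++count;
  }
  return (count + 1.0) / (n_perm + 1.0);
}
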