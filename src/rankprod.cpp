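#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// average-tie ranks of v into out (1-based ranks)
static void rank_avg(const std::vector<double>& v, std::vector<double>& out) {
  const int n = (int) v.size();
  static thread_local std::vector<int> idx;
  idx.resize(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&v](int a, int b) { return v[a] < v[b]; });
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && v[idx[j + 1]] == v[idx[i]]) ++j;
    double r = 0.5 * (i + j) + 1.0;  // average of positions i..j (1-based)
    for (int t = i; t <= j; ++t) out[idx[t]] = r;
    i = j + 1;
  }
}

// count, for each element of obs_sorted (ascending), how many elements of
// nullv (will be sorted in place) are <= it; adds into counts
static void add_tail_counts(std::vector<double>& nullv,
                            const NumericVector& obs_sorted,
                            std::vector<double>& counts) {
  std::sort(nullv.begin(), nullv.end());
  const int G = obs_sorted.size();
  const int N = (int) nullv.size();
  int p = 0;
  for (int g = 0; g < G; ++g) {
    while (p < N && nullv[p] <= obs_sorted[g]) ++p;
    counts[g] += p;
  }
}

// Null counts for the classical rank-product permutation scheme: each
// comparison column's rank vector is independently permuted across genes.
// logr: G x k matrix of log ranks; obs_sorted: ascending observed
// k*log(RP) values (with tie tolerance already added by the caller).
// [[Rcpp::export]]
NumericVector rp_null_counts_column(NumericMatrix logr,
                                    NumericVector obs_sorted, int n_perm) {
  const int G = logr.nrow(), k = logr.ncol();
  std::vector<double> counts(G, 0.0), acc(G), col(G);
  std::vector<int> perm(G);
  for (int b = 0; b < n_perm; ++b) {
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < G; ++i) perm[i] = i;
      for (int i = G - 1; i > 0; --i) {   // Fisher-Yates with R's RNG
        int w = (int) (unif_rand() * (i + 1));
        if (w > i) w = i;
        std::swap(perm[i], perm[w]);
      }
      for (int i = 0; i < G; ++i) acc[i] += logr(perm[i], j);
    }
    add_tail_counts(acc, obs_sorted, counts);
  }
  return wrap(counts);
}

// Null counts for the array-label permutation scheme: tumour/control
// labels are permuted across arrays, the all-pairs fold-change matrix is
// rebuilt and rank products recomputed. Preserves the within-array
// dependence that ties together comparisons sharing an array.
// M: G x A matrix of M-values; n_t = number of tumour arrays; sign = -1
// ranks descending (up direction), +1 ascending (down).
// [[Rcpp::export]]
NumericVector rp_null_counts_label(NumericMatrix M, int n_t, int n_perm,
                                   double sign, NumericVector obs_sorted) {
  const int G = M.nrow(), A = M.ncol();
  const int n_c = A - n_t;
  std::vector<double> counts(G, 0.0), acc(G), d(G), rk(G);
  std::vector<int> arr(A);
  for (int b = 0; b < n_perm; ++b) {
    for (int i = 0; i < A; ++i) arr[i] = i;
    for (int i = A - 1; i > 0; --i) {
      int w = (int) (unif_rand() * (i + 1));
      if (w > i) w = i;
      std::swap(arr[i], arr[w]);
    }
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int t = 0; t < n_t; ++t) {
      for (int c = 0; c < n_c; ++c) {
        const int ta = arr[t], ca = arr[n_t + c];
        for (int g = 0; g < G; ++g)
          d[g] = sign * (M(g, ta) - M(g, ca));
        rank_avg(d, rk);
        for (int g = 0; g < G; ++g) acc[g] += std::log(rk[g]);
      }
    }
    add_tail_counts(acc, obs_sorted, counts);
  }
  return wrap(counts);
}
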