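#include <Rcpp.h>
#include <vector>
#include <string>

// Base-pair maximisation (Nussinov-style) over a DNA-alphabet sequence.
// Pairs: A-T, G-C and optionally G-T wobble; hairpin loops must contain
// at least min_loop unpaired bases, i.e. i and j may pair only when
// j - i > min_loop.

static inline bool can_pair(char a, char b, bool wobble) {
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return true;
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return true;
  if (wobble && ((a == 'G' && b == 'T') || (a == 'T' && b == 'G'))) return true;
  return false;
}

// [[Rcpp::export]]
int nussinov_pairs(std::string seq, int min_loop = 3, bool wobble = true) {
  const int n = (int) seq.size();
  if (n < 2) return 0;
  std::vector<int> dp((size_t) n * n, 0);
  #define DP(i, j) dp[(size_t)(i) * n + (j)]
  for (int len = min_loop + 1; len < n; ++len) {
    for (int i = 0; i + len < n; ++i) {
      int j = i + len;
      int best = DP(i + 1, j);
      if (DP(i, j - 1) > best) best = DP(i, j - 1);
      if (can_pair(seq[i], seq[j], wobble)) {
        int v = DP(i + 1, j - 1) + 1;
        if (v > best) best = v;
      }
      for (int k = i; k < j; ++k) {
        int v = DP(i, k) + DP(k + 1, j);
        if (v > best) best = v;
      }
      DP(i, j) = best;
    }
  }
  int out = DP(0, n - 1);
  #undef DP
  return out;
}
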