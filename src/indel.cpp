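#include <Rcpp.h>
using namespace Rcpp;

// Insert/delete-only edit distance on code-point vectors.
// Equals |a| + |b| - 2 * LCS(a, b); substitutions are not allowed
// (one substitution costs a deletion plus an insertion).
static int indel_core(const IntegerVector& a, const IntegerVector& b) {
  const int n = a.size(), m = b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      int best = prev[j - 1] + (ai == b[j - 1] ? 1 : 0);
      if (prev[j] > best) best = prev[j];
      if (cur[j - 1] > best) best = cur[j - 1];
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return n + m - 2 * prev[m];
}

// [[Rcpp::export]]
IntegerVector indel_dist_pairs(List a_codes, List b_codes) {
  const int n = a_codes.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector a = a_codes[i], b = b_codes[i];
    out[i] = indel_core(a, b);
  }
  return out;
}

// Distance from one word to many candidates; candidates whose length
// differs from |a| by more than `cap` are reported as cap + 1 without
// running the DP (the distance is at least the length difference).
// [[Rcpp::export]]
IntegerVector indel_dist_one_to_many(IntegerVector a, List b_codes, int cap) {
  const int n = b_codes.size(), la = a.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector b = b_codes[i];
    if (cap >= 0 && abs((int)b.size() - la) > cap) {
      out[i] = cap + 1;
    } else {
      int d = indel_core(a, b);
      out[i] = (cap >= 0 && d > cap) ? cap + 1 : d;
    }
  }
  return out;
}
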