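#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Optimal Matching edit distance between two state-index sequences.
// a, b: 0-based indices into the substitution matrix.
// [[Rcpp::export]]
double om_dist_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                   double indel) {
  int m = a.size(), n = b.size();
  std::vector<double> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; j++) prev[j] = j * indel;
  for (int i = 1; i <= m; i++) {
    cur[0] = i * indel;
    for (int j = 1; j <= n; j++) {
      double d = prev[j - 1] + sub(a[i - 1], b[j - 1]);
      double e = prev[j] + indel;
      double f = cur[j - 1] + indel;
      double m1 = d < e ? d : e;
      cur[j] = m1 < f ? m1 : f;
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

// Full pairwise OM distance matrix. seqs: n x T matrix of 0-based profile
// indices; sub: pooled P x P substitution matrix over profiles.
// [[Rcpp::export]]
NumericMatrix pairwise_om_cpp(IntegerMatrix seqs, NumericMatrix sub,
                              double indel) {
  int n = seqs.nrow(), T = seqs.ncol();
  int P = sub.nrow();
  // flat copy of the substitution matrix for fast access
  std::vector<double> S((size_t)P * P);
  for (int j = 0; j < P; j++)
    for (int i = 0; i < P; i++) S[(size_t)j * P + i] = sub(i, j);
  NumericMatrix D(n, n);
  std::vector<int> ai(T), bi(T);
  std::vector<double> prev(T + 1), cur(T + 1);
  for (int x = 0; x < n; x++) {
    for (int t = 0; t < T; t++) ai[t] = seqs(x, t);
    for (int y = x + 1; y < n; y++) {
      bool same = true;
      for (int t = 0; t < T; t++) {
        bi[t] = seqs(y, t);
        if (bi[t] != ai[t]) same = false;
      }
      if (same) continue;  // identical sequences: distance 0
      for (int j = 0; j <= T; j++) prev[j] = j * indel;
      for (int i = 1; i <= T; i++) {
        cur[0] = i * indel;
        const double* srow = &S[(size_t)ai[i - 1]];  // column-strided access
        for (int j = 1; j <= T; j++) {
          double d = prev[j - 1] + srow[(size_t)bi[j - 1] * P];
          double e = prev[j] + indel;
          double f = cur[j - 1] + indel;
          double m1 = d < e ? d : e;
          cur[j] = m1 < f ? m1 : f;
        }
        std::swap(prev, cur);
      }
      D(x, y) = prev[T];
      D(y, x) = prev[T];
    }
    Rcpp::checkUserInterrupt();
  }
  return D;
}
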