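#include <Rcpp.h>
using namespace Rcpp;

// Maximum-score beat path over candidate envelope peaks.
//
// Maximizes sum(a[beat]) - w * sum((IBI[i+1] - IBI[i])^2) over all peak
// subsequences whose successive gaps lie in [ibi_lo, ibi_hi]. Because the
// penalty couples consecutive IBIs, the DP state is the last *edge*
// (previous peak, current peak); predecessors of an edge share its first
// endpoint. Peaks are assumed sorted by time.
//
// [[Rcpp::export]]
IntegerVector dp_beat_path(NumericVector t, NumericVector a,
                           double ibi_lo, double ibi_hi, double w) {
  int n = t.size();
  if (n < 2) return IntegerVector(0);

  // admissible predecessor index range [p1[k], p2[k]] for each peak k
  std::vector<int> p1(n), p2(n);
  int lo = 0;
  for (int k = 0; k < n; ++k) {
    while (lo < k && t[k] - t[lo] > ibi_hi) ++lo;
    int hi = k - 1;
    while (hi >= 0 && t[k] - t[hi] < ibi_lo) --hi;
    p1[k] = lo;
    p2[k] = hi;
  }

  std::vector< std::vector<double> > E(n);  // score of best path ending (j,k)
  std::vector< std::vector<int> > back(n);  // argmax predecessor i, -1 = start
  double best = R_NegInf;
  int bestk = -1, bestj = -1;

  for (int k = 0; k < n; ++k) {
    int m = p2[k] - p1[k] + 1;
    if (m <= 0) continue;
    E[k].assign(m, R_NegInf);
    back[k].assign(m, -1);
    for (int j = p1[k]; j <= p2[k]; ++j) {
      double ibi_jk = t[k] - t[j];
      double sc = a[j] + a[k];  // two-beat path starting at j
      int bi = -1;
      if (!E[j].empty()) {
        for (int i = p1[j]; i <= p2[j]; ++i) {
          double e = E[j][i - p1[j]];
          if (!R_FINITE(e)) continue;
          double d = ibi_jk - (t[j] - t[i]);
          double cand = e + a[k] - w * d * d;
          if (cand > sc) { sc = cand; bi = i; }
        }
      }
      E[k][j - p1[k]] = sc;
      back[k][j - p1[k]] = bi;
      if (sc > best) { best = sc; bestk = k; bestj = j; }
    }
  }
  if (bestk < 0) return IntegerVector(0);

  std::vector<int> path;
  int k = bestk, j = bestj;
  path.push_back(k);
  while (j >= 0) {
    path.push_back(j);
    int bi = back[k][j - p1[k]];
    k = j;
    j = bi;
  }
  std::reverse(path.begin(), path.end());
  IntegerVector out(path.size());
  for (size_t i = 0; i < path.size(); ++i) out[i] = path[i] + 1;
  return out;
}
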