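#include <Rcpp.h>
using namespace Rcpp;

// Greedy left-to-right extraction of qualifying intervals from prefix
// counts: at the leftmost start that admits any interval meeting all three
// thresholds, take the longest such interval, then continue after it.
// O(n^2) by construction; guarded to short sequences on the R side.
// [[Rcpp::export(name = ".cpp_oracle_scan")]]
IntegerMatrix cpp_oracle_scan(NumericVector prefC, NumericVector prefG,
                              NumericVector prefCpG, NumericVector prefValid,
                              int n, int minLen, double minGC, double minOE) {
  std::vector<int> starts, ends;
  int s = 0;
  while (s + minLen <= n) {
    int bestE = -1;
    for (int e = s + minLen; e <= n; ++e) {
      double c = prefC[e] - prefC[s];
      double g = prefG[e] - prefG[s];
      double valid = prefValid[e] - prefValid[s];
      if (valid <= 0 || c <= 0 || g <= 0) continue;
      double gc = 100.0 * (c + g) / valid;
      if (gc < minGC) continue;
      // CpG starts in [s, e-2]; prefCpG[k] = starts strictly before k-1
      double cpg = (e - s >= 2) ? prefCpG[e - 1] - prefCpG[s] : 0.0;
      double oe = cpg * valid / (c * g);
      if (oe >= minOE) bestE = e;
    }
    if (bestE > 0) {
      starts.push_back(s);
      ends.push_back(bestE);
      s = bestE;
    } else {
      ++s;
    }
  }
  IntegerMatrix out(starts.size(), 2);
  for (size_t i = 0; i < starts.size(); ++i) {
    out(i, 0) = starts[i];
    out(i, 1) = ends[i];
  }
  return out;
}

// First-order Markov chain over {A, C, G, T} (codes 1..4), driven by R's
// RNG so set.seed() makes the draw reproducible.
// [[Rcpp::export(name = ".cpp_markov_chain")]]
IntegerVector cpp_markov_chain(int n, NumericMatrix trans,
                               NumericVector init) {
  IntegerVector out(n);
  if (n == 0) return out;
  // cumulative rows
  double cumInit[4], cumTrans[4][4];
  double a = 0;
  for (int j = 0; j < 4; ++j) { a += init[j]; cumInit[j] = a; }
  for (int i = 0; i < 4; ++i) {
    a = 0;
    for (int j = 0; j < 4; ++j) { a += trans(i, j); cumTrans[i][j] = a; }
  }
  double u = unif_rand();
  int state = 3;
  for (int j = 0; j < 4; ++j) if (u <= cumInit[j]) { state = j; break; }
  out[0] = state + 1;
  for (int i = 1; i < n; ++i) {
    u = unif_rand();
    int nxt = 3;
    for (int j = 0; j < 4; ++j) if (u <= cumTrans[state][j]) { nxt = j; break; }
    state = nxt;
    out[i] = state + 1;
  }
  return out;
}
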