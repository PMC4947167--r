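#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Consume per-vertex successor lists in order, starting at `start`
// (1-based vertex codes).  The lists must encode a valid Eulerian path;
// the caller guarantees this via the arborescence construction.
// [[Rcpp::export]]
IntegerVector cpp_eulerian_walk(int start, List targets, int total_len) {
  int nv = targets.size();
  std::vector<std::vector<int> > tg(nv);
  std::vector<size_t> ptr(nv, 0);
  for (int v = 0; v < nv; ++v) {
    if (!Rf_isNull(targets[v])) {
      IntegerVector t = targets[v];
      tg[v] = std::vector<int>(t.begin(), t.end());
    }
  }
  IntegerVector out(total_len);
  int v = start;
  out[0] = v;
  for (int i = 1; i < total_len; ++i) {
    std::vector<int>& t = tg[v - 1];
    if (ptr[v - 1] >= t.size())
      stop("edge list exhausted at vertex %d (step %d)", v, i);
    v = t[ptr[v - 1]++];
    out[i] = v;
  }
  return out;
}

// 26-connectivity labelling of voxels with value > threshold.
// dims are the R array dims (column-major: first index fastest).
// [[Rcpp::export]]
IntegerVector cpp_label_components(NumericVector v, IntegerVector dims,
                                   double threshold) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  int n = d1 * d2 * d3;
  IntegerVector lab(n, 0);
  int next_label = 0;
  std::queue<int> q;
  for (int i = 0; i < n; ++i) {
    if (v[i] <= threshold || lab[i] != 0) continue;
    lab[i] = ++next_label;
    q.push(i);
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int i1 = c % d1, i2 = (c / d1) % d2, i3 = c / (d1 * d2);
      for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
          for (int e = -1; e <= 1; ++e) {
            if (!a && !b && !e) continue;
            int j1 = i1 + a, j2 = i2 + b, j3 = i3 + e;
            if (j1 < 0 || j1 >= d1 || j2 < 0 || j2 >= d2 ||
                j3 < 0 || j3 >= d3) continue;
            int j = j1 + d1 * (j2 + d2 * j3);
            if (v[j] > threshold && lab[j] == 0) {
              lab[j] = next_label;
              q.push(j);
            }
          }
    }
  }
  lab.attr("n_components") = next_label;
  return lab;
}

// Component counts over a grid of thresholds (26-connectivity).
// [[Rcpp::export]]
IntegerVector cpp_count_components(NumericVector v, IntegerVector dims,
                                   NumericVector thresholds) {
  int nt = thresholds.size();
  IntegerVector out(nt);
  for (int t = 0; t < nt; ++t) {
    IntegerVector lab = cpp_label_components(v, dims, thresholds[t]);
    out[t] = as<int>(lab.attr("n_components"));
  }
  return out;
}
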