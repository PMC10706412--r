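#include <Rcpp.h>
using namespace Rcpp;

static int find_root(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// Two-pass union-find connected-component labeling, 8-connectivity.
// Labels are compacted to 1..K in order of first occurrence in a
// column-major scan; relabeling downstream is by centroid reading order,
// so the scan order never leaks into results.
// [[Rcpp::export]]
IntegerMatrix cc_label_8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);
  int next = 1;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int neigh[4];
      int nn = 0;
      if (i > 0 && mask(i - 1, j)) neigh[nn++] = lab(i - 1, j);
      if (j > 0) {
        if (i > 0 && mask(i - 1, j - 1)) neigh[nn++] = lab(i - 1, j - 1);
        if (mask(i, j - 1)) neigh[nn++] = lab(i, j - 1);
        if (i + 1 < nr && mask(i + 1, j - 1)) neigh[nn++] = lab(i + 1, j - 1);
      }
      if (nn == 0) {
        parent.push_back(next);
        lab(i, j) = next++;
      } else {
        int m = neigh[0];
        for (int k = 1; k < nn; ++k) m = std::min(m, neigh[k]);
        lab(i, j) = m;
        for (int k = 0; k < nn; ++k) {
          int r1 = find_root(parent, m);
          int r2 = find_root(parent, neigh[k]);
          if (r1 != r2) parent[std::max(r1, r2)] = std::min(r1, r2);
        }
      }
    }
  }
  std::vector<int> newlab(next, 0);
  int K = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (lab(i, j)) {
        int r = find_root(parent, lab(i, j));
        if (!newlab[r]) newlab[r] = ++K;
        lab(i, j) = newlab[r];
      }
    }
  }
  return lab;
}
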