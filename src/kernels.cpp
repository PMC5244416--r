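#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Union-find with path compression for two-pass labeling.
static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Two-pass connected-component labeling of a logical matrix.
// connectivity: 4 or 8. Background (FALSE/NA) gets label 0; components are
// numbered 1..k in raster order of their first pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0); // parent[0] unused
  int next = 1;

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) != TRUE) { lab(i, j) = 0; continue; }
      // previously visited neighbours (column-major raster order):
      // (i-1, j), (i, j-1) and for 8-conn (i-1, j-1), (i+1, j-1)
      int nb[4]; int nn = 0;
      if (i > 0 && lab(i - 1, j) > 0) nb[nn++] = lab(i - 1, j);
      if (j > 0 && lab(i, j - 1) > 0) nb[nn++] = lab(i, j - 1);
      if (connectivity == 8 && j > 0) {
        if (i > 0 && lab(i - 1, j - 1) > 0) nb[nn++] = lab(i - 1, j - 1);
        if (i + 1 < nr && lab(i + 1, j - 1) > 0) nb[nn++] = lab(i + 1, j - 1);
      }
      if (nn == 0) {
        parent.push_back(next);
        lab(i, j) = next++;
      } else {
        int m = nb[0];
        for (int k = 1; k < nn; ++k) m = std::min(m, nb[k]);
        lab(i, j) = m;
        for (int k = 0; k < nn; ++k) uf_union(parent, m, nb[k]);
      }
    }
  }
  // Resolve equivalences and renumber densely.
  std::vector<int> newlab(parent.size(), 0);
  int k = 0;
  for (size_t x = 1; x < parent.size(); ++x) {
    int r = uf_find(parent, (int)x);
    if (newlab[r] == 0) newlab[r] = ++k;
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) > 0) lab(i, j) = newlab[uf_find(parent, lab(i, j))];
  return lab;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Exact squared Euclidean distance (in pixels) from every pixel to the nearest
// TRUE pixel of `target`. Pixels with no TRUE pixel anywhere -> Inf.
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(LogicalMatrix target) {
  int nr = target.nrow(), nc = target.ncol();
  // large finite sentinel instead of Inf: the envelope intersection
  // arithmetic must never see Inf - Inf (NaN would corrupt the transform)
  const double BIG = 1e15;
  NumericMatrix d(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      d(i, j) = (target(i, j) == TRUE) ? 0.0 : BIG;
  std::vector<double> f(std::max(nr, nc)), out(std::max(nr, nc));
  // transform along columns
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = d(i, j);
    dt1d(f, out, nr);
    for (int i = 0; i < nr; ++i) d(i, j) = out[i];
  }
  // then along rows
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = d(i, j);
    dt1d(f, out, nc);
    for (int j = 0; j < nc; ++j) d(i, j) = out[j];
  }
  // a target-free image yields sentinel-sized values -> report Inf
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (d(i, j) >= BIG) d(i, j) = std::numeric_limits<double>::infinity();
  return d;
}

// Fill holes: background pixels not reachable from the image border
// (4-connectivity through background) become foreground.
// [[Rcpp::export]]
LogicalMatrix cpp_fill_holes(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out(nr, nc);
  std::vector<char> reach((size_t)nr * nc, 0);
  std::queue<int> q;
  auto push = [&](int i, int j) {
    int idx = j * nr + i;
    if (!reach[idx] && mask(i, j) != TRUE) { reach[idx] = 1; q.push(idx); }
  };
  for (int i = 0; i < nr; ++i) { push(i, 0); push(i, nc - 1); }
  for (int j = 0; j < nc; ++j) { push(0, j); push(nr - 1, j); }
  while (!q.empty()) {
    int idx = q.front(); q.pop();
    int i = idx % nr, j = idx / nr;
    if (i > 0) push(i - 1, j);
    if (i + 1 < nr) push(i + 1, j);
    if (j > 0) push(i, j - 1);
    if (j + 1 < nc) push(i, j + 1);
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = (mask(i, j) == TRUE) || !reach[(size_t)j * nr + i];
  return out;
}
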