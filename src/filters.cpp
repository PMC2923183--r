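#include <Rcpp.h>
#include <vector>
#include <functional>
#include <algorithm>
using namespace Rcpp;

// Sliding-window order/mean statistics over square (2m+1)x(2m+1) masks.
// Windows are truncated at the image border; callers that must exclude a
// border rim do so afterwards (the rim width is a parameter of the chain,
// not of the filter).

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export(name = ".sliding_min_cpp")]]
NumericMatrix sliding_min_cpp(NumericMatrix x, int m) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    int j0 = clampi(j - m, 0, nc - 1), j1 = clampi(j + m, 0, nc - 1);
    for (int i = 0; i < nr; ++i) {
      int i0 = clampi(i - m, 0, nr - 1), i1 = clampi(i + m, 0, nr - 1);
      double v = x(i0, j0);
      for (int jj = j0; jj <= j1; ++jj)
        for (int ii = i0; ii <= i1; ++ii)
          if (x(ii, jj) < v) v = x(ii, jj);
      out(i, j) = v;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".sliding_max_cpp")]]
NumericMatrix sliding_max_cpp(NumericMatrix x, int m) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    int j0 = clampi(j - m, 0, nc - 1), j1 = clampi(j + m, 0, nc - 1);
    for (int i = 0; i < nr; ++i) {
      int i0 = clampi(i - m, 0, nr - 1), i1 = clampi(i + m, 0, nr - 1);
      double v = x(i0, j0);
      for (int jj = j0; jj <= j1; ++jj)
        for (int ii = i0; ii <= i1; ++ii)
          if (x(ii, jj) > v) v = x(ii, jj);
      out(i, j) = v;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".sliding_mean_cpp")]]
NumericMatrix sliding_mean_cpp(NumericMatrix x, int m) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    int j0 = clampi(j - m, 0, nc - 1), j1 = clampi(j + m, 0, nc - 1);
    for (int i = 0; i < nr; ++i) {
      int i0 = clampi(i - m, 0, nr - 1), i1 = clampi(i + m, 0, nr - 1);
      double s = 0.0;
      for (int jj = j0; jj <= j1; ++jj)
        for (int ii = i0; ii <= i1; ++ii)
          s += x(ii, jj);
      out(i, j) = s / ((i1 - i0 + 1) * (j1 - j0 + 1));
    }
  }
  return out;
}

// 8-connected component labelling of a logical mask (iterative DFS).
// Labels are 1..K in scan order of the first pixel met; 0 = background.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          int qj = pj + dj;
          if (qj < 0 || qj >= nc) continue;
          for (int di = -1; di <= 1; ++di) {
            int qi = pi + di;
            if ((di == 0 && dj == 0) || qi < 0 || qi >= nr) continue;
            if (mask(qi, qj) && lab(qi, qj) == 0) {
              lab(qi, qj) = next;
              stack.push_back(qi + qj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Number of 8-connected components with area >= min_area in (x >= T),
// for every threshold in `thresholds`, via one descending sweep with an
// incremental union-find (pixels activate as the threshold drops), so
// scanning ~1000 grid levels costs a single pass over the image.
// [[Rcpp::export(name = ".component_counts_cpp")]]
IntegerVector component_counts_cpp(NumericMatrix x, NumericVector thresholds,
                                   int min_area) {
  int nr = x.nrow(), nc = x.ncol(), n = nr * nc;
  int nT = thresholds.size();
  IntegerVector out(nT);

  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] > x[b]; });
  std::vector<int> tord(nT);
  for (int t = 0; t < nT; ++t) tord[t] = t;
  std::sort(tord.begin(), tord.end(),
            [&](int a, int b) { return thresholds[a] > thresholds[b]; });

  std::vector<int> parent(n, -1), area(n, 0);
  int n_large = 0;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto activate = [&](int p) {
    parent[p] = p; area[p] = 1;
    if (min_area <= 1) ++n_large;
    int pi = p % nr, pj = p / nr;
    for (int dj = -1; dj <= 1; ++dj) {
      int qj = pj + dj;
      if (qj < 0 || qj >= nc) continue;
      for (int di = -1; di <= 1; ++di) {
        int qi = pi + di;
        if ((di == 0 && dj == 0) || qi < 0 || qi >= nr) continue;
        int q = qi + qj * nr;
        if (parent[q] < 0) continue;            // neighbor not active yet
        int ra = find(p), rb = find(q);
        if (ra == rb) continue;
        int large_a = area[ra] >= min_area, large_b = area[rb] >= min_area;
        if (area[ra] < area[rb]) std::swap(ra, rb);
        parent[rb] = ra;
        area[ra] += area[rb];
        n_large += (area[ra] >= min_area) - large_a - large_b;
      }
    }
  };

  int k = 0;
  for (int t = 0; t < nT; ++t) {
    double T = thresholds[tord[t]];
    while (k < n && x[ord[k]] >= T) activate(ord[k++]);
    out[tord[t]] = n_large;
  }
  return out;
}
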