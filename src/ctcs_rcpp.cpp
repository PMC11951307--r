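#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Label connected foreground components of a logical matrix.
// connectivity: 4 (edge neighbours) or 8 (edge + diagonal neighbours).
// Labels are assigned in raster order; 0 marks background.
// [[Rcpp::export(name = ".labelComponents2D")]]
IntegerMatrix labelComponents2D(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);

  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};
  const int* dr = (connectivity == 4) ? dr4 : dr8;
  const int* dc = (connectivity == 4) ? dc4 : dc8;
  const int nnb = (connectivity == 4) ? 4 : 8;

  int next_label = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next_label;
      stack.clear();
      stack.push_back(i + j * nr);
      lab(i, j) = next_label;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          int ni = ci + dr[k], nj = cj + dc[k];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next_label;
            stack.push_back(ni + nj * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Minimum Euclidean distance from each query point to a reference point set.
// Both arguments are n x 3 matrices of world (mm) coordinates.
// [[Rcpp::export(name = ".minDistToSet")]]
NumericVector minDistToSet(const NumericMatrix& query, const NumericMatrix& ref) {
  const int nq = query.nrow(), nref = ref.nrow();
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf;
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    for (int j = 0; j < nref; ++j) {
      const double dx = qx - ref(j, 0), dy = qy - ref(j, 1), dz = qz - ref(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
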