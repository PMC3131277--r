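// Deterministic 3D connected-component labelling (BFS in scan order).

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim,
                          int connectivity) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  const R_xlen_t s2 = d1, s3 = (R_xlen_t)d1 * d2;
  IntegerVector lab(n);

  // neighbourhood offsets
  std::vector<int> di, dj, dk;
  for (int c = -1; c <= 1; ++c)
    for (int b = -1; b <= 1; ++b)
      for (int a = -1; a <= 1; ++a) {
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
  const size_t m = di.size();

  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t idx0 = 0; idx0 < n; ++idx0) {
    if (!mask[idx0] || lab[idx0]) continue;
    ++next;
    lab[idx0] = next;
    stack.clear();
    stack.push_back(idx0);
    while (!stack.empty()) {
      R_xlen_t idx = stack.back();
      stack.pop_back();
      int i = (int)(idx % d1);
      int j = (int)((idx / d1) % d2);
      int k = (int)(idx / s3);
      for (size_t t = 0; t < m; ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3)
          continue;
        R_xlen_t q = ii + (R_xlen_t)jj * s2 + (R_xlen_t)kk * s3;
        if (mask[q] && !lab[q]) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  lab.attr("n_labels") = next;
  return lab;
}
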