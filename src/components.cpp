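#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Label connected components of equal, non-zero value in an integer matrix.
// connectivity: 4 or 8. Cells equal to 0 are background and stay unlabelled.
// Returns an integer matrix of component labels (1..k, 0 = background).
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(const IntegerMatrix& m, int connectivity) {
  const int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  stack.reserve(nr * nc / 4 + 16);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (m(r, c) == 0 || lab(r, c) != 0) continue;
      const int val = m(r, c);
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int cr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nn; ++k) {
          const int r2 = cr + dr8[k], c2 = cc + dc8[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (lab(r2, c2) == 0 && m(r2, c2) == val) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
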