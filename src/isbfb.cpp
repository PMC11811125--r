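// Dynamic program deciding BFB-string membership by terminal-fold stripping:
// prefix b is reachable iff it is a reference prefix, or some m in
// [ceil(b/2), b-1] has the suffix equal to the mirror of the elements before
// position m and prefix m reachable.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".is_bfb_cpp")]]
bool is_bfb_cpp(IntegerVector seg, IntegerVector dir) {
  int b = seg.size();
  std::vector<char> ref(b + 1, 0), reach(b + 1, 0);
  bool r = true;
  for (int m = 1; m <= b; ++m) {
    r = r && seg[m - 1] == m && dir[m - 1] == 1;
    ref[m] = r;
  }
  for (int m = 1; m <= b; ++m) {
    if (ref[m]) { reach[m] = 1; continue; }
    for (int p = m - 1; 2 * p >= m; --p) {
      if (!reach[p]) continue;
      bool ok = true;
      for (int j = 1; j <= m - p; ++j) {
        if (seg[p + j - 1] != seg[p - j] || dir[p + j - 1] != -dir[p - j]) {
          ok = false; break;
        }
      }
      if (ok) { reach[m] = 1; break; }
    }
  }
  return reach[b] != 0;
}
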