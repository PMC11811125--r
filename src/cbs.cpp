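// Weighted circular binary segmentation scan.
//
// For the current stretch of labels the scan maximises a weighted two-sample
// t-like statistic over all arcs (i, j]; significance is assessed by
// permuting the (value, weight) pairs within the stretch.  Sequential early
// stopping abandons the permutation loop as soon as the exceedance count
// makes significance impossible at the requested alpha.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// max weighted arc statistic over (i, j], 0 <= i < j <= m; returns stat and arc
double max_arc_stat(const std::vector<double> &x, const std::vector<double> &w,
                    int min_width, int *bi, int *bj) {
  int m = (int)x.size();
  std::vector<double> cw(m + 1, 0.0), cwx(m + 1, 0.0);
  for (int i = 0; i < m; ++i) {
    cw[i + 1] = cw[i] + w[i];
    cwx[i + 1] = cwx[i] + w[i] * x[i];
  }
  double W = cw[m], S = cwx[m];
  double mu = S / W;
  double ss = 0.0;
  for (int i = 0; i < m; ++i) ss += w[i] * (x[i] - mu) * (x[i] - mu);
  double sd = std::sqrt(ss / W);
  if (sd < 1e-8) sd = 1e-8;
  double best = 0.0;
  int besti = -1, bestj = -1;
  for (int i = 0; i <= m - min_width; ++i) {
    for (int j = i + min_width; j <= m; ++j) {
      if (m - (j - i) < min_width) continue; // complement too small
      if (i == 0 && j == m) continue;
      double win = cw[j] - cw[i];
      double wout = W - win;
      if (win <= 0.0 || wout <= 0.0) continue;
      double min_ = (cwx[j] - cwx[i]) / win;
      double mout = (S - (cwx[j] - cwx[i])) / wout;
      double t = std::fabs(min_ - mout) / (sd * std::sqrt(1.0 / win + 1.0 / wout));
      if (t > best + 1e-12) { best = t; besti = i; bestj = j; }
    }
  }
  *bi = besti; *bj = bestj;
  return best;
}

} // namespace

// [[Rcpp::export(name = ".cbs_scan_cpp")]]
List cbs_scan_cpp(NumericVector x, NumericVector w, int min_width,
                  int nperm, double alpha, int seed) {
  int m = x.size();
  std::vector<double> xv(x.begin(), x.end()), wv(w.begin(), w.end());
  int bi, bj;
  double obs = max_arc_stat(xv, wv, min_width, &bi, &bj);
  if (bi < 0 || obs <= 1e-10)
    return List::create(_["significant"] = false, _["i"] = -1, _["j"] = -1,
                        _["stat"] = obs, _["pvalue"] = 1.0);
  // permutation test with early stopping (permute value/weight pairs jointly)
  std::vector<int> idx(m);
  for (int i = 0; i < m; ++i) idx[i] = i;
  // xorshift RNG seeded deterministically (independent of R's stream)
  unsigned long long state = (unsigned long long)seed * 2685821657736338717ULL + 1ULL;
  auto nextu = [&]() {
    state ^= state << 13; state ^= state >> 7; state ^= state << 17;
    return state;
  };
  int exceed = 0, done = 0;
  int allow = (int)std::floor(alpha * nperm); // > allow exceedances => not significant
  std::vector<double> px(m), pw(m);
  for (int p = 0; p < nperm; ++p) {
    for (int i = m - 1; i > 0; --i) {
      int j = (int)(nextu() % (unsigned long long)(i + 1));
      std::swap(idx[i], idx[j]);
    }
    for (int i = 0; i < m; ++i) { px[i] = xv[idx[i]]; pw[i] = wv[idx[i]]; }
    int di, dj;
    double st = max_arc_stat(px, pw, min_width, &di, &dj);
    ++done;
    if (st >= obs) {
      ++exceed;
      if (exceed > allow) break; // cannot reach significance
    }
  }
  double pval = (double)(exceed + 1) / (double)(done + 1);
  bool sig = exceed <= allow && done == nperm;
  return List::create(_["significant"] = sig, _["i"] = bi, _["j"] = bj,
                      _["stat"] = obs, _["pvalue"] = pval);
}
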