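#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// 2-D running median filter with edge replication.
// kr, kc are odd window dimensions (rows x cols).
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix x, int kr, int kc) {
  if (kr % 2 == 0 || kc % 2 == 0) stop("window dimensions must be odd");
  const int nr = x.nrow(), nc = x.ncol();
  const int hr = kr / 2, hc = kc / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)kr * kc);
  for (int j = 0; j < nr; ++j) {
    for (int i = 0; i < nc; ++i) {
      buf.clear();
      for (int dj = -hr; dj <= hr; ++dj) {
        int jj = j + dj;
        if (jj < 0) jj = 0; else if (jj >= nr) jj = nr - 1;
        for (int di = -hc; di <= hc; ++di) {
          int ii = i + di;
          if (ii < 0) ii = 0; else if (ii >= nc) ii = nc - 1;
          buf.push_back(x(jj, ii));
        }
      }
      size_t mid = buf.size() / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      out(j, i) = buf[mid];  // window size kr*kc is odd
    }
  }
  return out;
}

// Sum of absolute differences between B and A translated by t columns
// (content shifted right by t, out-of-bounds pixels read as zero),
// evaluated for every t in [tmin, tmax]. Returns the cost vector.
// [[Rcpp::export]]
NumericVector sad_translate_cpp(NumericMatrix a, NumericMatrix b,
                                int tmin, int tmax) {
  const int nr = a.nrow(), nc = a.ncol();
  if (b.nrow() != nr || b.ncol() != nc) stop("dimension mismatch");
  const int nt = tmax - tmin + 1;
  NumericVector cost(nt);
  for (int k = 0; k < nt; ++k) {
    const int t = tmin + k;
    double s = 0.0;
    for (int i = 0; i < nc; ++i) {
      const int isrc = i - t;  // column of a that lands on column i
      if (isrc < 0 || isrc >= nc) {
        for (int j = 0; j < nr; ++j) s += std::abs(b(j, i));
      } else {
        for (int j = 0; j < nr; ++j) s += std::abs(a(j, isrc) - b(j, i));
      }
    }
    cost[k] = s;
  }
  return cost;
}
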