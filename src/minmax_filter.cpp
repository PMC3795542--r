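#include <Rcpp.h>
using namespace Rcpp;

static inline int clampi(int i, int n) {
  return i < 0 ? 0 : (i >= n ? n - 1 : i);
}

// Flat min/max filter over an explicit offset list with edge-replicate
// sampling: out-of-frame offsets are clamped to the nearest border pixel,
// so extrema on monotone edges see no spurious values.
// dr/dc are 0-based row/column offsets added to the output pixel location.
// Iterates offset-major with column-sequential access for cache locality.
// [[Rcpp::export]]
NumericMatrix minmax_filter_cpp(NumericMatrix f, IntegerVector dr,
                                IntegerVector dc, bool take_max) {
  const int H = f.nrow(), W = f.ncol(), K = dr.size();
  NumericMatrix out(H, W);
  std::fill(out.begin(), out.end(), take_max ? R_NegInf : R_PosInf);
  const double *fp = f.begin();
  double *op = out.begin();
  for (int k = 0; k < K; ++k) {
    const int drk = dr[k], dck = dc[k];
    for (int c = 0; c < W; ++c) {
      const double *src = fp + (size_t)clampi(c + dck, W) * H;
      double *o = op + (size_t)c * H;
      // rows split into clamped head/tail and an unclamped middle run
      const int lo = std::min(std::max(-drk, 0), H);
      const int hi = std::max(std::min(H - drk, H), lo);
      if (take_max) {
        const double head = src[0], tail = src[H - 1];
        for (int r = 0; r < lo; ++r) if (head > o[r]) o[r] = head;
        for (int r = lo; r < hi; ++r) {
          const double x = src[r + drk];
          if (x > o[r]) o[r] = x;
        }
        for (int r = hi; r < H; ++r) if (tail > o[r]) o[r] = tail;
      } else {
        const double head = src[0], tail = src[H - 1];
        for (int r = 0; r < lo; ++r) if (head < o[r]) o[r] = head;
        for (int r = lo; r < hi; ++r) {
          const double x = src[r + drk];
          if (x < o[r]) o[r] = x;
        }
        for (int r = hi; r < H; ++r) if (tail < o[r]) o[r] = tail;
      }
    }
  }
  return out;
}
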