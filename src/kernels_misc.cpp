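// Batched linear resize (align-corners, separable weights) and instance
// normalisation, kept in C++ to avoid sparse-matrix coercions and large
// temporaries on the tape.  Layout as in kernels_conv.cpp.

#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC optimize("O3","unroll-loops")
#endif

#include <Rcpp.h>
#include <cstring>
#include <vector>
#include <cmath>
using namespace Rcpp;

// per-axis interpolation tables: lower index and weight per target index
static void axis_table(int Ss, int Sd, std::vector<int>& i0,
                       std::vector<double>& w) {
  i0.resize(Sd);
  w.resize(Sd);
  for (int i = 0; i < Sd; ++i) {
    double f = Sd == 1 ? 0.0 : (double)i * (Ss - 1) / (Sd - 1);
    int lo = (int)std::floor(f);
    if (lo > Ss - 2) lo = Ss - 2;
    if (lo < 0) lo = 0;
    double ww = f - lo;
    if (std::abs(ww) < 1e-12) ww = 0.0;
    if (std::abs(ww - 1) < 1e-12) ww = 1.0;
    i0[i] = lo;
    w[i] = ww;
  }
}

// resample one axis (the first) of a (S x m) plane set: out (Sd x m)
static void resize_axis_fw(const double* x, int Ss, std::size_t m,
                           const std::vector<int>& i0,
                           const std::vector<double>& w, double* y) {
  const int Sd = (int)i0.size();
  for (std::size_t c = 0; c < m; ++c) {
    const double* xc = x + (std::size_t)Ss * c;
    double* yc = y + (std::size_t)Sd * c;
    for (int i = 0; i < Sd; ++i)
      yc[i] = (1 - w[i]) * xc[i0[i]] + w[i] * xc[i0[i] + 1 < Ss ? i0[i] + 1 : i0[i]];
  }
}

static void resize_axis_bw(const double* g, int Ss, std::size_t m,
                           const std::vector<int>& i0,
                           const std::vector<double>& w, double* gx) {
  const int Sd = (int)i0.size();
  for (std::size_t c = 0; c < m; ++c) {
    const double* gc = g + (std::size_t)Sd * c;
    double* xc = gx + (std::size_t)Ss * c;
    for (int i = 0; i < Sd; ++i) {
      xc[i0[i]] += (1 - w[i]) * gc[i];
      const int hi = i0[i] + 1 < Ss ? i0[i] + 1 : i0[i];
      xc[hi] += w[i] * gc[i];
    }
  }
}

// transpose the leading axis behind the remaining ones:
// in (S1 x rest x C-planes) -> out (rest x S1 x ...): we implement the
// standard "rotate axes" trick so each axis becomes leading once.
static void rotate_axis(const double* x, int S1, std::size_t rest,
                        std::size_t planes, double* y) {
  // x viewed as (S1, rest) per plane -> y as (rest, S1)
  for (std::size_t p = 0; p < planes; ++p) {
    const double* xp = x + S1 * rest * p;
    double* yp = y + S1 * rest * p;
    for (std::size_t r = 0; r < rest; ++r)
      for (int i = 0; i < S1; ++i) yp[r + rest * (std::size_t)i] = xp[i + S1 * r];
  }
}

// [[Rcpp::export(name = ".cpp_resize_fw")]]
NumericMatrix cpp_resize_fw(const NumericMatrix& x, const IntegerVector& src,
                            const IntegerVector& dst, int batch) {
  const int n = src.size();
  const int C = x.ncol();
  std::size_t np_src = 1, np_dst = 1;
  for (int a = 0; a < n; ++a) { np_src *= src[a]; np_dst *= dst[a]; }
  const std::size_t planes = (std::size_t)batch * C;
  // gather all planes contiguously: x columns already hold batch-stacked
  // items; a plane here is one (item, channel) volume
  std::vector<double> buf(np_src * planes), buf2;
  {
    const double* xp = &x(0, 0);
    for (int c = 0; c < C; ++c)
      for (int bb = 0; bb < batch; ++bb)
        std::memcpy(buf.data() + np_src * ((std::size_t)bb + batch * (std::size_t)c),
                    xp + np_src * ((std::size_t)bb + batch * (std::size_t)c),
                    np_src * sizeof(double));
  }
  std::vector<int> i0;
  std::vector<double> w;
  std::vector<int> cur(src.begin(), src.end());
  for (int a = 0; a < n; ++a) {
    // resample current leading axis, then rotate it to the back
    axis_table(cur[0], dst[a], i0, w);
    std::size_t rest = 1;
    for (int b = 1; b < n; ++b) rest *= cur[b];
    buf2.assign((std::size_t)dst[a] * rest * planes, 0.0);
    resize_axis_fw(buf.data(), cur[0], rest * planes, i0, w, buf2.data());
    // rotate: (Sd, rest) -> (rest, Sd) per plane
    buf.assign(buf2.size(), 0.0);
    rotate_axis(buf2.data(), dst[a], rest, planes, buf.data());
    for (int b = 0; b < n - 1; ++b) cur[b] = cur[b + 1];
    cur[n - 1] = dst[a];
  }
  NumericMatrix out((int)(np_dst * batch), C);
  double* op = &out(0, 0);
  std::memcpy(op, buf.data(), np_dst * planes * sizeof(double));
  return out;
}

// [[Rcpp::export(name = ".cpp_resize_bw")]]
NumericMatrix cpp_resize_bw(const NumericMatrix& g, const IntegerVector& src,
                            const IntegerVector& dst, int batch) {
  const int n = src.size();
  const int C = g.ncol();
  std::size_t np_src = 1, np_dst = 1;
  for (int a = 0; a < n; ++a) { np_src *= src[a]; np_dst *= dst[a]; }
  const std::size_t planes = (std::size_t)batch * C;
  std::vector<double> buf(np_dst * planes), buf2;
  std::memcpy(buf.data(), &g(0, 0), np_dst * planes * sizeof(double));
  std::vector<int> i0;
  std::vector<double> w;
  // reverse the forward axis pipeline: undo rotations and axis resamplings
  std::vector<int> cur(dst.begin(), dst.end());
  for (int a = n - 1; a >= 0; --a) {
    // cur holds the shape after the full forward; walking backwards, the
    // last forward step resampled axis a and rotated it to the back
    // un-rotate: (rest, Sd) -> (Sd, rest)
    std::size_t rest = 1;
    for (int b = 0; b < n - 1; ++b) rest *= cur[b];
    const int Sd = cur[n - 1];
    buf2.assign(buf.size(), 0.0);
    // inverse of rotate_axis(Sd, rest): y[r + rest*i] = x[i + Sd*r]
    for (std::size_t p = 0; p < planes; ++p) {
      const double* xp = buf.data() + (std::size_t)Sd * rest * p;
      double* yp = buf2.data() + (std::size_t)Sd * rest * p;
      for (std::size_t r = 0; r < rest; ++r)
        for (int i = 0; i < Sd; ++i) yp[i + Sd * r] = xp[r + rest * (std::size_t)i];
    }
    // backward of the axis resampling: scatter (Sd -> Ss)
    const int Ss = src[a];
    axis_table(Ss, Sd, i0, w);
    buf.assign((std::size_t)Ss * rest * planes, 0.0);
    resize_axis_bw(buf2.data(), Ss, rest * planes, i0, w, buf.data());
    for (int b = n - 1; b > 0; --b) cur[b] = cur[b - 1];
    cur[0] = Ss;
  }
  NumericMatrix gx((int)(np_src * batch), C);
  std::memcpy(&gx(0, 0), buf.data(), np_src * planes * sizeof(double));
  return gx;
}

// [[Rcpp::export(name = ".cpp_instnorm_fw")]]
List cpp_instnorm_fw(const NumericMatrix& x, int batch, double eps) {
  const int C = x.ncol();
  const std::size_t m = (std::size_t)x.nrow() / batch;
  const std::size_t nb = (std::size_t)batch * C;
  NumericMatrix y(x.nrow(), C);
  NumericVector s(nb);
  const double* xp = &x(0, 0);
  double* yp = &y(0, 0);
  for (std::size_t blk = 0; blk < nb; ++blk) {
    const double* xb = xp + m * blk;
    double* yb = yp + m * blk;
    double mu = 0.0;
    for (std::size_t t = 0; t < m; ++t) mu += xb[t];
    mu /= m;
    double var = 0.0;
    for (std::size_t t = 0; t < m; ++t) {
      const double d = xb[t] - mu;
      var += d * d;
    }
    const double sd = std::sqrt(var / m + eps);
    s[blk] = sd;
    const double inv = 1.0 / sd;
    for (std::size_t t = 0; t < m; ++t) yb[t] = (xb[t] - mu) * inv;
  }
  return List::create(_["y"] = y, _["s"] = s);
}

// [[Rcpp::export(name = ".cpp_instnorm_bw")]]
NumericMatrix cpp_instnorm_bw(const NumericMatrix& y, const NumericVector& s,
                              const NumericMatrix& g, int batch) {
  const int C = y.ncol();
  const std::size_t m = (std::size_t)y.nrow() / batch;
  const std::size_t nb = (std::size_t)batch * C;
  NumericMatrix gx(y.nrow(), C);
  const double* yp = &y(0, 0);
  const double* gp = &g(0, 0);
  double* op = &gx(0, 0);
  for (std::size_t blk = 0; blk < nb; ++blk) {
    const double* yb = yp + m * blk;
    const double* gb = gp + m * blk;
    double* ob = op + m * blk;
    double gm = 0.0, gym = 0.0;
    for (std::size_t t = 0; t < m; ++t) {
      gm += gb[t];
      gym += gb[t] * yb[t];
    }
    gm /= m;
    gym /= m;
    const double inv = 1.0 / s[blk];
    for (std::size_t t = 0; t < m; ++t)
      ob[t] = (gb[t] - gm - yb[t] * gym) * inv;
  }
  return gx;
}
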