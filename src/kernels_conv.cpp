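// im2col / col2im kernels for batched n-D convolution (n = 2, 3).
// The column matrix built in the forward pass is cached on the tape and
// reused by the backward pass (weight gradient and col2im input scatter).
//
// Layouts: data ((batch*npos) x C) column-major with batch items stacked as
// row blocks, voxels column-major within an item (axis 1 fastest); weights
// ((k^n * inch) x outch) with row r = ch + inch * ko, ko = d1 + k*d2
// [+ k*k*d3].  The column matrix is written in place (no intermediate copy);
// only out-of-image (padding) entries are zeroed.

#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC optimize("O3","unroll-loops")
#endif

#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

static inline int out_extent(int S, int k, int stride, int pad) {
  return (S + 2 * pad - k) / stride + 1;
}

// valid output-index range [o0, o1] so that 0 <= o*stride - pad + d < S
static inline void valid_range(int S, int So, int stride, int pad, int d,
                               int& o0, int& o1) {
  int lo = pad - d;
  o0 = lo <= 0 ? 0 : (lo + stride - 1) / stride;
  int hi = S - 1 + pad - d;
  o1 = hi < 0 ? -1 : hi / stride;
  if (o1 > So - 1) o1 = So - 1;
}

static inline void zero_fill(double* p, std::size_t count) {
  if (count) std::memset(p, 0, count * sizeof(double));
}

// [[Rcpp::export(name = ".cpp_im2col")]]
NumericMatrix cpp_im2col(const NumericMatrix& x, const IntegerVector& sdim,
                         int k, int stride, int pad, int batch) {
  const int n = sdim.size();
  const int inch = x.ncol();
  const int H = sdim[0];
  const int W = sdim[1];
  const int D = n == 3 ? sdim[2] : 1;
  const int Ho = out_extent(H, k, stride, pad);
  const int Wo = out_extent(W, k, stride, pad);
  const int Do = n == 3 ? out_extent(D, k, stride, pad) : 1;
  const int kd = n == 3 ? k : 1;
  const std::size_t nout = (std::size_t)Ho * Wo * Do;
  const std::size_t nrow = nout * batch;
  NumericMatrix cols((int)nrow, (int)((std::size_t)k * k * kd * inch));
  const double* xp0 = &x(0, 0);
  double* cp0 = &cols(0, 0);
  const std::size_t npos_in = (std::size_t)H * W * D;
  for (int bb = 0; bb < batch; ++bb) {
    const double* xp = xp0 + (std::size_t)bb * npos_in;
    double* cp = cp0 + (std::size_t)bb * nout;
    for (int dz = 0; dz < kd; ++dz) {
      int oz0 = 0, oz1 = Do - 1;
      if (n == 3) valid_range(D, Do, stride, pad, dz, oz0, oz1);
      for (int dj = 0; dj < k; ++dj) {
        int oj0, oj1;
        valid_range(W, Wo, stride, pad, dj, oj0, oj1);
        for (int di = 0; di < k; ++di) {
          int oi0, oi1;
          valid_range(H, Ho, stride, pad, di, oi0, oi1);
          const int len = oi1 >= oi0 ? oi1 - oi0 + 1 : 0;
          const int ii0 = oi0 * stride - pad + di;
          for (int ch = 0; ch < inch; ++ch) {
            const int ko = di + k * (dj + k * dz);
            double* col = cp + nrow * (ch + (std::size_t)inch * ko);
            const double* xch = xp + npos_in * ch * batch;
            for (int oz = 0; oz < Do; ++oz) {
              const int zz = (n == 3) ? oz * stride - pad + dz : 0;
              double* plane = col + (std::size_t)Ho * Wo * oz;
              if (oz < oz0 || oz > oz1 || len == 0 || oj1 < oj0) {
                zero_fill(plane, (std::size_t)Ho * Wo);
                continue;
              }
              // stripes before / after the valid oj range
              zero_fill(plane, (std::size_t)Ho * oj0);
              zero_fill(plane + (std::size_t)Ho * (oj1 + 1),
                        (std::size_t)Ho * (Wo - 1 - oj1));
              for (int oj = oj0; oj <= oj1; ++oj) {
                const int jj = oj * stride - pad + dj;
                const double* src =
                    xch + (std::size_t)H * (jj + (std::size_t)W * zz) + ii0;
                double* dst = plane + (std::size_t)Ho * oj;
                zero_fill(dst, oi0);
                zero_fill(dst + oi1 + 1, Ho - 1 - oi1);
                dst += oi0;
                if (stride == 1) {
                  std::memcpy(dst, src, sizeof(double) * len);
                } else {
                  for (int t = 0; t < len; ++t)
                    dst[t] = src[(std::size_t)t * stride];
                }
              }
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export(name = ".cpp_col2im")]]
NumericMatrix cpp_col2im(const NumericMatrix& gcols, const IntegerVector& sdim,
                         int inch, int k, int stride, int pad, int batch) {
  const int n = sdim.size();
  const int H = sdim[0];
  const int W = sdim[1];
  const int D = n == 3 ? sdim[2] : 1;
  const int Ho = out_extent(H, k, stride, pad);
  const int Wo = out_extent(W, k, stride, pad);
  const int Do = n == 3 ? out_extent(D, k, stride, pad) : 1;
  const int kd = n == 3 ? k : 1;
  const std::size_t nout = (std::size_t)Ho * Wo * Do;
  const std::size_t nrow = nout * batch;
  const std::size_t npos_in = (std::size_t)H * W * D;
  NumericMatrix gx((int)(npos_in * batch), inch);
  const double* cp0 = &gcols(0, 0);
  double* gp0 = &gx(0, 0);
  zero_fill(gp0, npos_in * batch * inch);
  for (int bb = 0; bb < batch; ++bb) {
    const double* cp = cp0 + (std::size_t)bb * nout;
    double* gp = gp0 + (std::size_t)bb * npos_in;
    for (int dz = 0; dz < kd; ++dz) {
      int oz0 = 0, oz1 = Do - 1;
      if (n == 3) valid_range(D, Do, stride, pad, dz, oz0, oz1);
      for (int dj = 0; dj < k; ++dj) {
        int oj0, oj1;
        valid_range(W, Wo, stride, pad, dj, oj0, oj1);
        for (int di = 0; di < k; ++di) {
          int oi0, oi1;
          valid_range(H, Ho, stride, pad, di, oi0, oi1);
          const int len = oi1 - oi0 + 1;
          if (len <= 0 || oj1 < oj0 || oz1 < oz0) continue;
          const int ii0 = oi0 * stride - pad + di;
          for (int ch = 0; ch < inch; ++ch) {
            const int ko = di + k * (dj + k * dz);
            const double* col = cp + nrow * (ch + (std::size_t)inch * ko);
            double* gch = gp + npos_in * ch * batch;
            for (int oz = oz0; oz <= oz1; ++oz) {
              const int zz = (n == 3) ? oz * stride - pad + dz : 0;
              for (int oj = oj0; oj <= oj1; ++oj) {
                const int jj = oj * stride - pad + dj;
                double* dst =
                    gch + (std::size_t)H * (jj + (std::size_t)W * zz) + ii0;
                const double* src =
                    col + oi0 + (std::size_t)Ho * (oj + (std::size_t)Wo * oz);
                if (stride == 1) {
                  for (int t = 0; t < len; ++t) dst[t] += src[t];
                } else {
                  for (int t = 0; t < len; ++t)
                    dst[(std::size_t)t * stride] += src[t];
                }
              }
            }
          }
        }
      }
    }
  }
  return gx;
}
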