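// Direct (im2col-free) batched convolution for stride 1, the hot path of
// the encoder/decoder stacks.  Works tap-by-tap with contiguous inner loops
// blocked four output channels at a time, so each image plane stays
// cache-resident and no large scratch matrices are allocated.  Layout as in
// kernels_conv.cpp.

#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC optimize("O3","unroll-loops")
#endif

#include <Rcpp.h>
#include <cstring>
#include <vector>
using namespace Rcpp;

static inline int dext(int S, int k, int pad) { return S + 2 * pad - k + 1; }

static inline void dvalid(int S, int So, int pad, int d, int& o0, int& o1) {
  o0 = pad - d > 0 ? pad - d : 0;
  o1 = S - 1 + pad - d;
  if (o1 > So - 1) o1 = So - 1;
}

template <typename T>
static void dconv_fw_core(const T* xp0, int xrows, int inch,
                          const T* wp, int wld, int outch, const T* bp,
                          const IntegerVector& sdim, int k, int pad,
                          int batch, T* op0) {
  const int n = sdim.size();
  const int H = sdim[0], W = sdim[1], D = n == 3 ? sdim[2] : 1;
  const int Ho = dext(H, k, pad), Wo = dext(W, k, pad),
            Do = n == 3 ? dext(D, k, pad) : 1;
  const int kd = n == 3 ? k : 1;
  const std::size_t npos_in = (std::size_t)H * W * D;
  const std::size_t npos_out = (std::size_t)Ho * Wo * Do;
  for (int oc = 0; oc < outch; ++oc) {
    T* dst = op0 + npos_out * batch * (std::size_t)oc;
    const T bv = bp[oc];
    for (std::size_t t = 0; t < npos_out * (std::size_t)batch; ++t) dst[t] = bv;
  }
  for (int bb = 0; bb < batch; ++bb) {
    const T* xb = xp0 + (std::size_t)bb * npos_in;
    T* ob = op0 + (std::size_t)bb * npos_out;
    for (int dz = 0; dz < kd; ++dz) {
      int oz0 = 0, oz1 = Do - 1;
      if (n == 3) dvalid(D, Do, pad, dz, oz0, oz1);
      for (int dj = 0; dj < k; ++dj) {
        int oj0, oj1;
        dvalid(W, Wo, pad, dj, oj0, oj1);
        for (int di = 0; di < k; ++di) {
          int oi0, oi1;
          dvalid(H, Ho, pad, di, oi0, oi1);
          const int len = oi1 - oi0 + 1;
          if (len <= 0 || oj1 < oj0 || oz1 < oz0) continue;
          const int ko = di + k * (dj + k * dz);
          const int ii0 = oi0 - pad + di;
          // one output stream per pass, four input streams: keeps the
          // read-modify-write traffic on the destination minimal
          for (int oc = 0; oc < outch; ++oc) {
            T* oc_p = ob + npos_out * (std::size_t)batch * oc;
            int ic = 0;
            for (; ic + 4 <= inch; ic += 4) {
              const T* x0 = xb + npos_in * (std::size_t)batch * ic;
              const T* x1 = xb + npos_in * (std::size_t)batch * (ic + 1);
              const T* x2 = xb + npos_in * (std::size_t)batch * (ic + 2);
              const T* x3 = xb + npos_in * (std::size_t)batch * (ic + 3);
              const std::size_t wb = (std::size_t)inch * ko +
                                     (std::size_t)wld * oc;
              const T w0 = wp[ic + wb];
              const T w1 = wp[ic + 1 + wb];
              const T w2 = wp[ic + 2 + wb];
              const T w3 = wp[ic + 3 + wb];
              for (int oz = oz0; oz <= oz1; ++oz) {
                const int zz = (n == 3) ? oz - pad + dz : 0;
                for (int oj = oj0; oj <= oj1; ++oj) {
                  const int jj = oj - pad + dj;
                  const std::size_t xoff =
                      (std::size_t)H * (jj + (std::size_t)W * zz) + ii0;
                  T* dst =
                      oc_p + (std::size_t)Ho * (oj + (std::size_t)Wo * oz) + oi0;
                  const T* s0 = x0 + xoff;
                  const T* s1 = x1 + xoff;
                  const T* s2 = x2 + xoff;
                  const T* s3 = x3 + xoff;
                  for (int t = 0; t < len; ++t)
                    dst[t] += w0 * s0[t] + w1 * s1[t] + w2 * s2[t] + w3 * s3[t];
                }
              }
            }
            for (; ic < inch; ++ic) {
              const T* xc = xb + npos_in * (std::size_t)batch * ic;
              const T w = wp[(ic + (std::size_t)inch * ko) +
                                  (std::size_t)wld * oc];
              for (int oz = oz0; oz <= oz1; ++oz) {
                const int zz = (n == 3) ? oz - pad + dz : 0;
                for (int oj = oj0; oj <= oj1; ++oj) {
                  const int jj = oj - pad + dj;
                  const T* src =
                      xc + (std::size_t)H * (jj + (std::size_t)W * zz) + ii0;
                  T* dst =
                      oc_p + (std::size_t)Ho * (oj + (std::size_t)Wo * oz) + oi0;
                  for (int t = 0; t < len; ++t) dst[t] += w * src[t];
                }
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_dconv_fw")]]
NumericMatrix cpp_dconv_fw(const NumericMatrix& x, const IntegerVector& sdim,
                           const NumericMatrix& Wm, const NumericVector& b,
                           int k, int pad, int batch, bool single) {
  const int n = sdim.size();
  const int H = sdim[0], W = sdim[1], D = n == 3 ? sdim[2] : 1;
  const int Ho = dext(H, k, pad), Wo = dext(W, k, pad),
            Do = n == 3 ? dext(D, k, pad) : 1;
  const std::size_t npos_out =
      (std::size_t)Ho * Wo * (n == 3 ? Do : 1) * batch;
  const int outch = Wm.ncol();
  NumericMatrix out((int)npos_out, outch);
  if (!single) {
    dconv_fw_core<double>(&x(0, 0), x.nrow(), x.ncol(), &Wm(0, 0), Wm.nrow(),
                          outch, &b[0], sdim, k, pad, batch, &out(0, 0));
  } else {
    std::vector<float> xf(x.begin(), x.end());
    std::vector<float> wf(Wm.begin(), Wm.end());
    std::vector<float> bf(b.begin(), b.end());
    std::vector<float> of(npos_out * (std::size_t)outch);
    dconv_fw_core<float>(xf.data(), x.nrow(), x.ncol(), wf.data(), Wm.nrow(),
                         outch, bf.data(), sdim, k, pad, batch, of.data());
    double* op = &out(0, 0);
    for (std::size_t i = 0; i < of.size(); ++i) op[i] = of[i];
  }
  return out;
}

template <typename T>
static void dconv_bw_core(const T* xp0, int inch, const T* wp, int wld,
                          int outch, const T* gp0, const IntegerVector& sdim,
                          int k, int pad, int batch, bool need_gx, T* gxp,
                          T* gwp, T* gbp) {
  const int n = sdim.size();
  const int H = sdim[0], W = sdim[1], D = n == 3 ? sdim[2] : 1;
  const int Ho = dext(H, k, pad), Wo = dext(W, k, pad),
            Do = n == 3 ? dext(D, k, pad) : 1;
  const int kd = n == 3 ? k : 1;
  const std::size_t npos_in = (std::size_t)H * W * D;
  const std::size_t npos_out = (std::size_t)Ho * Wo * Do;
  if (need_gx)
    std::memset(gxp, 0, npos_in * batch * inch * sizeof(T));
  for (int oc = 0; oc < outch; ++oc) {
    const T* g = gp0 + npos_out * (std::size_t)batch * oc;
    T acc = 0.0;
    for (std::size_t t = 0; t < npos_out * (std::size_t)batch; ++t) acc += g[t];
    gbp[oc] = acc;
  }
  for (int bb = 0; bb < batch; ++bb) {
    const T* xb = xp0 + (std::size_t)bb * npos_in;
    const T* gob = gp0 + (std::size_t)bb * npos_out;
    T* gxb = need_gx ? (gxp + (std::size_t)bb * npos_in) : nullptr;
    for (int dz = 0; dz < kd; ++dz) {
      int oz0 = 0, oz1 = Do - 1;
      if (n == 3) dvalid(D, Do, pad, dz, oz0, oz1);
      for (int dj = 0; dj < k; ++dj) {
        int oj0, oj1;
        dvalid(W, Wo, pad, dj, oj0, oj1);
        for (int di = 0; di < k; ++di) {
          int oi0, oi1;
          dvalid(H, Ho, pad, di, oi0, oi1);
          const int len = oi1 - oi0 + 1;
          if (len <= 0 || oj1 < oj0 || oz1 < oz0) continue;
          const int ko = di + k * (dj + k * dz);
          const int ii0 = oi0 - pad + di;
          for (int ic = 0; ic < inch; ++ic) {
            const T* xc = xb + npos_in * (std::size_t)batch * ic;
            T* gxc =
                need_gx ? gxb + npos_in * (std::size_t)batch * ic : nullptr;
            int oc = 0;
            for (; oc + 4 <= outch; oc += 4) {
              const T w0 = wp[(ic + (std::size_t)inch * ko) +
                                   (std::size_t)wld * oc];
              const T w1 = wp[(ic + (std::size_t)inch * ko) +
                                   (std::size_t)wld * (oc + 1)];
              const T w2 = wp[(ic + (std::size_t)inch * ko) +
                                   (std::size_t)wld * (oc + 2)];
              const T w3 = wp[(ic + (std::size_t)inch * ko) +
                                   (std::size_t)wld * (oc + 3)];
              const T* g0 = gob + npos_out * (std::size_t)batch * oc;
              const T* g1 = gob + npos_out * (std::size_t)batch * (oc + 1);
              const T* g2 = gob + npos_out * (std::size_t)batch * (oc + 2);
              const T* g3 = gob + npos_out * (std::size_t)batch * (oc + 3);
              T a0 = 0, a1 = 0, a2 = 0, a3 = 0;
              for (int oz = oz0; oz <= oz1; ++oz) {
                const int zz = (n == 3) ? oz - pad + dz : 0;
                for (int oj = oj0; oj <= oj1; ++oj) {
                  const int jj = oj - pad + dj;
                  const std::size_t xoff =
                      (std::size_t)H * (jj + (std::size_t)W * zz) + ii0;
                  const std::size_t goff =
                      (std::size_t)Ho * (oj + (std::size_t)Wo * oz) + oi0;
                  const T* xs = xc + xoff;
                  const T* q0 = g0 + goff;
                  const T* q1 = g1 + goff;
                  const T* q2 = g2 + goff;
                  const T* q3 = g3 + goff;
                  if (need_gx) {
                    T* gd = gxc + xoff;
                    for (int t = 0; t < len; ++t) {
                      const T xv = xs[t];
                      a0 += xv * q0[t];
                      a1 += xv * q1[t];
                      a2 += xv * q2[t];
                      a3 += xv * q3[t];
                      gd[t] += w0 * q0[t] + w1 * q1[t] + w2 * q2[t] + w3 * q3[t];
                    }
                  } else {
                    for (int t = 0; t < len; ++t) {
                      const T xv = xs[t];
                      a0 += xv * q0[t];
                      a1 += xv * q1[t];
                      a2 += xv * q2[t];
                      a3 += xv * q3[t];
                    }
                  }
                }
              }
              const std::size_t wr = ic + (std::size_t)inch * ko;
              gwp[wr + (std::size_t)wld * oc] += a0;
              gwp[wr + (std::size_t)wld * (oc + 1)] += a1;
              gwp[wr + (std::size_t)wld * (oc + 2)] += a2;
              gwp[wr + (std::size_t)wld * (oc + 3)] += a3;
            }
            for (; oc < outch; ++oc) {
              const T w = wp[(ic + (std::size_t)inch * ko) +
                                  (std::size_t)wld * oc];
              const T* gc = gob + npos_out * (std::size_t)batch * oc;
              T wacc = 0.0;
              for (int oz = oz0; oz <= oz1; ++oz) {
                const int zz = (n == 3) ? oz - pad + dz : 0;
                for (int oj = oj0; oj <= oj1; ++oj) {
                  const int jj = oj - pad + dj;
                  const T* xs =
                      xc + (std::size_t)H * (jj + (std::size_t)W * zz) + ii0;
                  const T* gs =
                      gc + (std::size_t)Ho * (oj + (std::size_t)Wo * oz) + oi0;
                  if (need_gx) {
                    T* gd =
                        gxc + (std::size_t)H * (jj + (std::size_t)W * zz) + ii0;
                    for (int t = 0; t < len; ++t) {
                      wacc += xs[t] * gs[t];
                      gd[t] += w * gs[t];
                    }
                  } else {
                    for (int t = 0; t < len; ++t) wacc += xs[t] * gs[t];
                  }
                }
              }
              gwp[(ic + (std::size_t)inch * ko) + (std::size_t)wld * oc] += wacc;
            }
          }
        }
      }
    }
  }
}

// Pad the output-channel dimension to a multiple of four with zero weights
// and zero gradients, so the blocked inner loops always engage; the padded
// channels contribute nothing.
template <typename T>
static void dconv_bw_padded(const T* xp, int inch, const T* wp, int wld,
                            int outch, const T* gp, std::size_t grows,
                            const IntegerVector& sdim, int k, int pad,
                            int batch, bool need_gx, T* gxp, T* gwp, T* gbp) {
  if (outch % 4 == 0 || outch < 3) {
    dconv_bw_core<T>(xp, inch, wp, wld, outch, gp, sdim, k, pad, batch,
                     need_gx, gxp, gwp, gbp);
    return;
  }
  const int oc4 = ((outch + 3) / 4) * 4;
  std::vector<T> wpad((std::size_t)wld * oc4, (T)0);
  std::vector<T> gpad(grows * oc4, (T)0);
  std::vector<T> gwpad((std::size_t)wld * oc4, (T)0);
  std::vector<T> gbpad(oc4, (T)0);
  std::copy(wp, wp + (std::size_t)wld * outch, wpad.begin());
  std::copy(gp, gp + grows * outch, gpad.begin());
  dconv_bw_core<T>(xp, inch, wpad.data(), wld, oc4, gpad.data(), sdim, k,
                   pad, batch, need_gx, gxp, gwpad.data(), gbpad.data());
  std::copy(gwpad.begin(), gwpad.begin() + (std::size_t)wld * outch, gwp);
  std::copy(gbpad.begin(), gbpad.begin() + outch, gbp);
}

// [[Rcpp::export(name = ".cpp_dconv_bw")]]
List cpp_dconv_bw(const NumericMatrix& x, const IntegerVector& sdim,
                  const NumericMatrix& Wm, const NumericMatrix& gout, int k,
                  int pad, int batch, bool need_gx, bool single) {
  const int inch = x.ncol();
  const int outch = Wm.ncol();
  const std::size_t grows = (std::size_t)gout.nrow();
  NumericMatrix gW(Wm.nrow(), outch);
  NumericVector gb(outch);
  NumericMatrix gx(need_gx ? x.nrow() : 1, need_gx ? inch : 1);
  if (!single) {
    dconv_bw_padded<double>(&x(0, 0), inch, &Wm(0, 0), Wm.nrow(), outch,
                            &gout(0, 0), grows, sdim, k, pad, batch, need_gx,
                            &gx(0, 0), &gW(0, 0), &gb[0]);
  } else {
    std::vector<float> xf(x.begin(), x.end());
    std::vector<float> wf(Wm.begin(), Wm.end());
    std::vector<float> gf(gout.begin(), gout.end());
    std::vector<float> gxf(need_gx ? (std::size_t)x.nrow() * inch : 1);
    std::vector<float> gwf((std::size_t)Wm.nrow() * outch, 0.0f);
    std::vector<float> gbf(outch, 0.0f);
    dconv_bw_padded<float>(xf.data(), inch, wf.data(), Wm.nrow(), outch,
                           gf.data(), grows, sdim, k, pad, batch, need_gx,
                           gxf.data(), gwf.data(), gbf.data());
    if (need_gx) {
      double* p = &gx(0, 0);
      for (std::size_t i = 0; i < gxf.size(); ++i) p[i] = gxf[i];
    }
    double* pw = &gW(0, 0);
    for (std::size_t i = 0; i < gwf.size(); ++i) pw[i] = gwf[i];
    for (int i = 0; i < outch; ++i) gb[i] = gbf[i];
  }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}
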