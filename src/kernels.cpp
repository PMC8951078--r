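// Compiled numeric kernels for the differentiable geometric substrate and the
// convolutional networks.  Tensor layout convention (shared with the R code):
//   * a feature map / image with n spatial axes is an (npos x C) matrix whose
//     rows enumerate voxels in column-major order (axis 1 fastest);
//   * a coordinate grid / displacement field is an (npos x n) matrix whose
//     column j holds the normalised coordinate along axis j, in [-1, 1] with
//     align-corners convention (index 0 <-> -1, index S-1 <-> +1);
//   * convolution weights are ((k^n * inch) x outch) matrices with row index
//     r = ch + inch * ko, where ko enumerates the kernel offsets
//     column-major (ko = d1 + k*d2 [+ k*k*d3]).
// All kernels are single-threaded and deterministic.

#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC optimize("O3","unroll-loops")
#endif

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Grid sampling (pull warping), linear / nearest, align-corners, border clamp
// ---------------------------------------------------------------------------

// Map a normalised coordinate to a fractional index, with border clamping.
// "snap" pulls near-integer fractional indices onto the exact node so that
// resampling at an identity grid reproduces the input bit-for-bit.
static inline void coord_to_index(double c, int S, double& f, bool& inrange) {
  f = (c + 1.0) * 0.5 * (S - 1);
  inrange = f > 0.0 && f < (double)(S - 1);
  if (f < 0.0) f = 0.0;
  if (f > (double)(S - 1)) f = (double)(S - 1);
  const double r = std::round(f);
  if (std::abs(f - r) < 1e-7) f = r;
}

// [[Rcpp::export(name = ".cpp_grid_sample_fw")]]
arma::mat cpp_grid_sample_fw(const arma::mat& x, const arma::ivec& sdim,
                             const arma::mat& grid, bool nearest) {
  const int n = sdim.n_elem;
  const int C = x.n_cols;
  const int npos = grid.n_rows;
  arma::mat out(npos, C);
  const int H = sdim[0], W = sdim[1];
  if (n == 2) {
    for (int p = 0; p < npos; ++p) {
      double f1, f2;
      bool in1, in2;
      coord_to_index(grid(p, 0), H, f1, in1);
      coord_to_index(grid(p, 1), W, f2, in2);
      if (nearest) {
        const int i = (int)std::round(f1), j = (int)std::round(f2);
        for (int c = 0; c < C; ++c) out(p, c) = x(i + H * j, c);
      } else {
        int i0 = std::min((int)std::floor(f1), H - 2); if (i0 < 0) i0 = 0;
        int j0 = std::min((int)std::floor(f2), W - 2); if (j0 < 0) j0 = 0;
        const int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1);
        const double w1 = f1 - i0, w2 = f2 - j0;
        const double a00 = (1 - w1) * (1 - w2), a10 = w1 * (1 - w2);
        const double a01 = (1 - w1) * w2, a11 = w1 * w2;
        const int p00 = i0 + H * j0, p10 = i1 + H * j0;
        const int p01 = i0 + H * j1, p11 = i1 + H * j1;
        for (int c = 0; c < C; ++c)
          out(p, c) = a00 * x(p00, c) + a10 * x(p10, c) + a01 * x(p01, c) +
                      a11 * x(p11, c);
      }
    }
  } else {
    const int D = sdim[2];
    for (int p = 0; p < npos; ++p) {
      double f1, f2, f3;
      bool in1, in2, in3;
      coord_to_index(grid(p, 0), H, f1, in1);
      coord_to_index(grid(p, 1), W, f2, in2);
      coord_to_index(grid(p, 2), D, f3, in3);
      if (nearest) {
        const int i = (int)std::round(f1), j = (int)std::round(f2),
                  z = (int)std::round(f3);
        for (int c = 0; c < C; ++c) out(p, c) = x(i + H * (j + W * z), c);
      } else {
        int i0 = std::min((int)std::floor(f1), H - 2); if (i0 < 0) i0 = 0;
        int j0 = std::min((int)std::floor(f2), W - 2); if (j0 < 0) j0 = 0;
        int z0 = std::min((int)std::floor(f3), D - 2); if (z0 < 0) z0 = 0;
        const int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1),
                  z1 = std::min(z0 + 1, D - 1);
        const double w1 = f1 - i0, w2 = f2 - j0, w3 = f3 - z0;
        for (int c = 0; c < C; ++c) {
          double acc = 0.0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                const double w = (di ? w1 : 1 - w1) * (dj ? w2 : 1 - w2) *
                                 (dz ? w3 : 1 - w3);
                const int pos = (di ? i1 : i0) +
                                H * ((dj ? j1 : j0) + W * (dz ? z1 : z0));
                acc += w * x(pos, c);
              }
          out(p, c) = acc;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_grid_sample_bw")]]
List cpp_grid_sample_bw(const arma::mat& x, const arma::ivec& sdim,
                        const arma::mat& grid, const arma::mat& gout,
                        bool need_gx, bool need_ggrid) {
  const int n = sdim.n_elem;
  const int C = x.n_cols;
  const int npos = grid.n_rows;
  arma::mat gx, ggrid;
  if (need_gx) gx.zeros(x.n_rows, C);
  if (need_ggrid) ggrid.zeros(npos, n);
  const int H = sdim[0], W = sdim[1];
  if (n == 2) {
    const double s1 = 0.5 * (H - 1), s2 = 0.5 * (W - 1);
    for (int p = 0; p < npos; ++p) {
      double f1, f2;
      bool in1, in2;
      coord_to_index(grid(p, 0), H, f1, in1);
      coord_to_index(grid(p, 1), W, f2, in2);
      int i0 = std::min((int)std::floor(f1), H - 2); if (i0 < 0) i0 = 0;
      int j0 = std::min((int)std::floor(f2), W - 2); if (j0 < 0) j0 = 0;
      const int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1);
      const double w1 = f1 - i0, w2 = f2 - j0;
      const int p00 = i0 + H * j0, p10 = i1 + H * j0;
      const int p01 = i0 + H * j1, p11 = i1 + H * j1;
      double d1 = 0.0, d2 = 0.0;
      for (int c = 0; c < C; ++c) {
        const double g = gout(p, c);
        if (need_gx) {
          gx(p00, c) += g * (1 - w1) * (1 - w2);
          gx(p10, c) += g * w1 * (1 - w2);
          gx(p01, c) += g * (1 - w1) * w2;
          gx(p11, c) += g * w1 * w2;
        }
        if (need_ggrid) {
          d1 += g * ((x(p10, c) - x(p00, c)) * (1 - w2) +
                     (x(p11, c) - x(p01, c)) * w2);
          d2 += g * ((x(p01, c) - x(p00, c)) * (1 - w1) +
                     (x(p11, c) - x(p10, c)) * w1);
        }
      }
      if (need_ggrid) {
        ggrid(p, 0) = in1 ? d1 * s1 : 0.0;
        ggrid(p, 1) = in2 ? d2 * s2 : 0.0;
      }
    }
  } else {
    const int D = sdim[2];
    const double s1 = 0.5 * (H - 1), s2 = 0.5 * (W - 1), s3 = 0.5 * (D - 1);
    for (int p = 0; p < npos; ++p) {
      double f1, f2, f3;
      bool in1, in2, in3;
      coord_to_index(grid(p, 0), H, f1, in1);
      coord_to_index(grid(p, 1), W, f2, in2);
      coord_to_index(grid(p, 2), D, f3, in3);
      int i0 = std::min((int)std::floor(f1), H - 2); if (i0 < 0) i0 = 0;
      int j0 = std::min((int)std::floor(f2), W - 2); if (j0 < 0) j0 = 0;
      int z0 = std::min((int)std::floor(f3), D - 2); if (z0 < 0) z0 = 0;
      const int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1),
                z1 = std::min(z0 + 1, D - 1);
      const double w1 = f1 - i0, w2 = f2 - j0, w3 = f3 - z0;
      double d1 = 0.0, d2 = 0.0, d3 = 0.0;
      for (int dz = 0; dz < 2; ++dz)
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const double u1 = di ? w1 : 1 - w1, u2 = dj ? w2 : 1 - w2,
                         u3 = dz ? w3 : 1 - w3;
            const double sg1 = di ? 1.0 : -1.0, sg2 = dj ? 1.0 : -1.0,
                         sg3 = dz ? 1.0 : -1.0;
            const int pos = (di ? i1 : i0) +
                            H * ((dj ? j1 : j0) + W * (dz ? z1 : z0));
            for (int c = 0; c < C; ++c) {
              const double g = gout(p, c);
              if (need_gx) gx(pos, c) += g * u1 * u2 * u3;
              if (need_ggrid) {
                const double xv = x(pos, c);
                d1 += g * xv * sg1 * u2 * u3;
                d2 += g * xv * u1 * sg2 * u3;
                d3 += g * xv * u1 * u2 * sg3;
              }
            }
          }
      if (need_ggrid) {
        ggrid(p, 0) = in1 ? d1 * s1 : 0.0;
        ggrid(p, 1) = in2 ? d2 * s2 : 0.0;
        ggrid(p, 2) = in3 ? d3 * s3 : 0.0;
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggrid"] = ggrid);
}
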