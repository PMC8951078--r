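// Elementwise activation kernels (kept in C++ to avoid large temporary
// allocations on the autodiff tape).

#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC optimize("O3","unroll-loops")
#endif

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_lrelu_fw")]]
NumericMatrix cpp_lrelu_fw(const NumericMatrix& x, double slope) {
  NumericMatrix y(x.nrow(), x.ncol());
  const double* xp = &x(0, 0);
  double* yp = &y(0, 0);
  const std::size_t nn = (std::size_t)x.nrow() * x.ncol();
  for (std::size_t i = 0; i < nn; ++i)
    yp[i] = xp[i] > 0 ? xp[i] : slope * xp[i];
  return y;
}

// [[Rcpp::export(name = ".cpp_lrelu_bw")]]
NumericMatrix cpp_lrelu_bw(const NumericMatrix& x, const NumericMatrix& g,
                           double slope) {
  NumericMatrix gx(x.nrow(), x.ncol());
  const double* xp = &x(0, 0);
  const double* gp = &g(0, 0);
  double* op = &gx(0, 0);
  const std::size_t nn = (std::size_t)x.nrow() * x.ncol();
  for (std::size_t i = 0; i < nn; ++i)
    op[i] = xp[i] > 0 ? gp[i] : slope * gp[i];
  return gx;
}
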