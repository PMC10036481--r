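#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Per-pixel temporal median of an H x W x T stack.
// Avoids T apply() calls in R, which dominate runtime for large stacks.
// [[Rcpp::export(name = ".median_stack_cpp")]]
NumericMatrix median_stack_cpp(NumericVector stack) {
  IntegerVector dims = stack.attr("dim");
  if (dims.size() != 3) stop("expected a 3-d array (H x W x T)");
  const R_xlen_t H = dims[0], W = dims[1], T = dims[2];
  const R_xlen_t HW = H * W;
  NumericMatrix out(H, W);
  std::vector<double> buf(T);
  const double *p = REAL(stack);
  for (R_xlen_t i = 0; i < HW; ++i) {
    for (R_xlen_t t = 0; t < T; ++t) buf[t] = p[i + t * HW];
    const R_xlen_t k = T / 2;
    std::nth_element(buf.begin(), buf.begin() + k, buf.end());
    double med = buf[k];
    if (T % 2 == 0) {
      std::nth_element(buf.begin(), buf.begin() + k - 1, buf.begin() + k);
      med = 0.5 * (med + buf[k - 1]);
    }
    out[i] = med;
  }
  return out;
}
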