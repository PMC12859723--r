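#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Dilated convolution features (PPV + max) for one scan.
//
// x: samples x channels matrix of input series.
// For each kernel the shared weight vector is applied to each selected
// channel at the same (dilated) lags, the channel responses are summed,
// the bias added, and two features emitted over the valid output
// positions: the proportion of strictly positive values (PPV) and the
// maximum. With padding the series is conceptually zero-padded by
// ((len - 1) * dilation) / 2 on each side.
//
// Accumulation runs tap-by-tap over a contiguous output buffer so the
// inner loop is a stride-1 fused multiply-add.
// [[Rcpp::export]]
NumericVector kernel_transform_cpp(NumericMatrix x, List kernels) {
  const int n = x.nrow();
  const int nk = kernels.size();
  const double* xp = REAL(x);
  NumericVector out(2 * nk);
  std::vector<double> acc;

  for (int k = 0; k < nk; ++k) {
    List ker = kernels[k];
    NumericVector w = ker["weights"];
    const double bias = as<double>(ker["bias"]);
    const int dil = as<int>(ker["dilation"]);
    const bool padding = as<bool>(ker["padding"]);
    IntegerVector ch = ker["channels"];
    const int klen = w.size();
    const int span = (klen - 1) * dil;
    const int pad = padding ? span / 2 : 0;
    const int start = -pad;                 // first output position
    const int nout = n + 2 * pad - span;    // number of output positions

    if (nout < 1) {
      out[2 * k] = NA_REAL;
      out[2 * k + 1] = NA_REAL;
      continue;
    }

    acc.assign(nout, bias);
    double* a = acc.data();
    for (int c = 0; c < ch.size(); ++c) {
      const double* xc = xp + (ptrdiff_t)(ch[c] - 1) * n;
      for (int j = 0; j < klen; ++j) {
        const double wj = w[j];
        // output position t0 uses sample idx = start + t0 + j * dil;
        // valid sample range [0, n) maps to t0 in [lo, hi)
        int lo = -(start + j * dil);
        if (lo < 0) lo = 0;
        int hi = n - (start + j * dil);
        if (hi > nout) hi = nout;
        const double* xs = xc + start + j * dil + lo;
        for (int t = lo; t < hi; ++t) a[t] += wj * xs[t - lo];
      }
    }
    int npos = 0;
    double mx = a[0];
    for (int t = 0; t < nout; ++t) {
      if (a[t] > 0) ++npos;
      if (a[t] > mx) mx = a[t];
    }
    out[2 * k] = (double)npos / (double)nout;
    out[2 * k + 1] = mx;
  }
  return out;
}
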