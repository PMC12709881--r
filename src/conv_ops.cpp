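// Compiled kernels for the convolution layers: im2col-based forward pass and
// the matching backward pass (weight, bias and data gradients). Feature maps
// are (H, W, C) arrays (column-major, matching R); weights arrive as the
// (Cin*k*k, Cout) matrix produced by convWeightMat() with channel fastest
// within each tap and taps ordered (ki, kj).

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2colPad(const arma::cube& x, const int k, const int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(static_cast<size_t>(H) * W, static_cast<size_t>(C) * k * k,
                 arma::fill::zeros);
  const double* xp = x.memptr();
  double* cp = cols.memptr();
  const size_t nrow = static_cast<size_t>(H) * W;
  for (int kj = 0; kj < k; ++kj) {
    for (int ki = 0; ki < k; ++ki) {
      const int i0 = std::max(0, pad - ki);            // valid output rows
      const int i1 = std::min(H, H + pad - ki);
      if (i1 <= i0) continue;
      for (int ci = 0; ci < C; ++ci) {
        const size_t col = ci + static_cast<size_t>(C) * (ki + k * kj);
        double* dst0 = cp + col * nrow;
        const double* src0 = xp + static_cast<size_t>(ci) * H * W;
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - pad;
          if (sj < 0 || sj >= W) continue;
          std::copy(src0 + static_cast<size_t>(sj) * H + (i0 + ki - pad),
                    src0 + static_cast<size_t>(sj) * H + (i1 + ki - pad),
                    dst0 + static_cast<size_t>(j) * H + i0);
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export(name = ".convForwardCpp")]]
List convForwardCpp(const arma::cube& x, const arma::mat& Wm,
                    const arma::vec& b, const int k, const bool wantCols) {
  const int H = x.n_rows, W = x.n_cols;
  const int cout = Wm.n_cols;
  const int pad = (k - 1) / 2;
  arma::mat cols = im2colPad(x, k, pad);
  arma::mat outMat = cols * Wm;
  outMat.each_row() += b.t();
  arma::cube out(H, W, cout);
  std::copy(outMat.memptr(), outMat.memptr() + outMat.n_elem, out.memptr());
  if (wantCols) return List::create(_["out"] = out, _["cols"] = cols);
  return List::create(_["out"] = out);
}

// [[Rcpp::export(name = ".convBackwardCpp")]]
List convBackwardCpp(const arma::cube& dout, const arma::mat& Wm,
                     const arma::mat& cols, const int k, const int cin) {
  const int H = dout.n_rows, W = dout.n_cols, cout = dout.n_slices;
  const int pad = (k - 1) / 2;
  const arma::mat domat(const_cast<double*>(dout.memptr()),
                        static_cast<size_t>(H) * W, cout, false, true);
  arma::mat dWm = cols.t() * domat;
  arma::vec db = arma::sum(domat, 0).t();
  arma::mat dcols = domat * Wm.t();
  arma::cube dx(H, W, cin, arma::fill::zeros);
  const double* sp = dcols.memptr();
  double* dp = dx.memptr();
  const size_t nrow = static_cast<size_t>(H) * W;
  for (int kj = 0; kj < k; ++kj) {
    for (int ki = 0; ki < k; ++ki) {
      const int i0 = std::max(0, pad - ki);
      const int i1 = std::min(H, H + pad - ki);
      if (i1 <= i0) continue;
      for (int ci = 0; ci < cin; ++ci) {
        const size_t col = ci + static_cast<size_t>(cin) * (ki + k * kj);
        const double* src0 = sp + col * nrow;
        double* dst0 = dp + static_cast<size_t>(ci) * H * W;
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - pad;
          if (sj < 0 || sj >= W) continue;
          const double* s = src0 + static_cast<size_t>(j) * H + i0;
          double* d = dst0 + static_cast<size_t>(sj) * H + (i0 + ki - pad);
          for (int i = i0; i < i1; ++i) *d++ += *s++;
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dWm"] = dWm, _["db"] = db);
}

// 2x2 stride-2 max pooling with argmax bookkeeping for the backward pass.
// [[Rcpp::export(name = ".maxpoolForwardCpp")]]
List maxpoolForwardCpp(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int h2 = H / 2, w2 = W / 2;
  arma::cube out(h2, w2, C);
  IntegerVector pick(static_cast<size_t>(h2) * w2 * C);
  size_t p = 0;
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < w2; ++j) {
      for (int i = 0; i < h2; ++i, ++p) {
        const double a = x(2 * i, 2 * j, c), bq = x(2 * i + 1, 2 * j, c);
        const double cq = x(2 * i, 2 * j + 1, c), dq = x(2 * i + 1, 2 * j + 1, c);
        double m = a; int which = 0;
        if (bq > m) { m = bq; which = 1; }
        if (cq > m) { m = cq; which = 2; }
        if (dq > m) { m = dq; which = 3; }
        out(i, j, c) = m;
        pick[p] = which;
      }
    }
  }
  return List::create(_["out"] = out, _["pick"] = pick);
}

// [[Rcpp::export(name = ".maxpoolBackwardCpp")]]
arma::cube maxpoolBackwardCpp(const arma::cube& dout, const IntegerVector& pick) {
  const int h2 = dout.n_rows, w2 = dout.n_cols, C = dout.n_slices;
  arma::cube dx(2 * h2, 2 * w2, C, arma::fill::zeros);
  size_t p = 0;
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < w2; ++j) {
      for (int i = 0; i < h2; ++i, ++p) {
        const int which = pick[p];
        dx(2 * i + (which == 1 || which == 3 ? 1 : 0),
           2 * j + (which >= 2 ? 1 : 0), c) = dout(i, j, c);
      }
    }
  }
  return dx;
}
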