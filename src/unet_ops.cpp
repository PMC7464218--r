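// Low-level tensor ops for the encoder-decoder network.
//
// Feature maps are stored as (H*W) x C matrices in column-major pixel order
// (pixel index = row + col*H, 0-based), matching as.vector() on an R matrix.
// All convolutions are 3x3, stride 1, zero ("same") padding.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// Expand X (HW x C) into its 3x3 neighbourhood matrix (HW x 9C).
// Column k*C + ch holds, at pixel (r, c), the value X[(r+dr) + (c+dc)*H, ch]
// where k enumerates offsets (dc, dr) in column-major order over {-1,0,1}^2.
static mat im2col3(const mat& X, const int H, const int W) {
  const int C = X.n_cols;
  mat Xc(static_cast<uword>(H) * W, 9 * C, fill::zeros);
  int k = 0;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr, ++k) {
      const int r0 = std::max(0, -dr), r1 = H - 1 - std::max(0, dr);
      const int c0 = std::max(0, -dc), c1 = W - 1 - std::max(0, dc);
      if (r1 < r0 || c1 < c0) continue;
      const size_t len = static_cast<size_t>(r1 - r0 + 1);
      for (int ch = 0; ch < C; ++ch) {
        const double* src = X.colptr(ch);
        double* dst = Xc.colptr(k * C + ch);
        for (int c = c0; c <= c1; ++c) {
          std::memcpy(dst + r0 + static_cast<size_t>(c) * H,
                      src + (r0 + dr) + static_cast<size_t>(c + dc) * H,
                      sizeof(double) * len);
        }
      }
    }
  }
  return Xc;
}

// Adjoint of im2col3: scatter-add neighbourhood gradients back to pixels.
static mat col2im3(const mat& dXc, const int H, const int W) {
  const int C = dXc.n_cols / 9;
  mat dX(static_cast<uword>(H) * W, C, fill::zeros);
  int k = 0;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr, ++k) {
      const int r0 = std::max(0, -dr), r1 = H - 1 - std::max(0, dr);
      const int c0 = std::max(0, -dc), c1 = W - 1 - std::max(0, dc);
      if (r1 < r0 || c1 < c0) continue;
      for (int ch = 0; ch < C; ++ch) {
        double* dst = dX.colptr(ch);
        const double* src = dXc.colptr(k * C + ch);
        for (int c = c0; c <= c1; ++c) {
          double* d = dst + (r0 + dr) + static_cast<size_t>(c + dc) * H;
          const double* s = src + r0 + static_cast<size_t>(c) * H;
          for (int i = 0; i <= r1 - r0; ++i) d[i] += s[i];
        }
      }
    }
  }
  return dX;
}

// [[Rcpp::export(name = ".conv3_fwd")]]
arma::mat conv3_fwd(const arma::mat& X, const arma::mat& Wm,
                    const arma::rowvec& b, const int H, const int W) {
  mat Y = im2col3(X, H, W) * Wm;
  Y.each_row() += b;
  return Y;
}

// Forward pass that also returns the expanded neighbourhood matrix, so the
// backward pass can reuse it for the weight gradient.
// [[Rcpp::export(name = ".conv3_fwd_cache")]]
Rcpp::List conv3_fwd_cache(const arma::mat& X, const arma::mat& Wm,
                           const arma::rowvec& b, const int H, const int W) {
  mat Xc = im2col3(X, H, W);
  mat Y = Xc * Wm;
  Y.each_row() += b;
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("Xc") = Xc);
}

// [[Rcpp::export(name = ".conv3_bwd")]]
Rcpp::List conv3_bwd(const arma::mat& Xc, const arma::mat& Wm,
                     const arma::mat& dY, const int H, const int W,
                     const bool want_dx) {
  mat dW = Xc.t() * dY;
  rowvec db = sum(dY, 0);
  if (!want_dx) {
    return Rcpp::List::create(Rcpp::Named("dX") = R_NilValue,
                              Rcpp::Named("dW") = dW,
                              Rcpp::Named("db") = db);
  }
  mat dX = col2im3(dY * Wm.t(), H, W);
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// 2x2 max pooling, stride 2. Returns pooled map and 1-based argmax source
// rows (per output pixel and channel) for the backward pass.
// [[Rcpp::export(name = ".pool2_fwd")]]
Rcpp::List pool2_fwd(const arma::mat& X, const int H, const int W) {
  const int C = X.n_cols, H2 = H / 2, W2 = W / 2;
  mat Y(static_cast<uword>(H2) * W2, C);
  umat which(static_cast<uword>(H2) * W2, C);
  for (int ch = 0; ch < C; ++ch) {
    const double* x = X.colptr(ch);
    double* y = Y.colptr(ch);
    uword* wv = which.colptr(ch);
    for (int c2 = 0; c2 < W2; ++c2) {
      for (int r2 = 0; r2 < H2; ++r2) {
        const size_t i00 = (2 * r2)     + static_cast<size_t>(2 * c2) * H;
        const size_t i10 = (2 * r2 + 1) + static_cast<size_t>(2 * c2) * H;
        const size_t i01 = (2 * r2)     + static_cast<size_t>(2 * c2 + 1) * H;
        const size_t i11 = (2 * r2 + 1) + static_cast<size_t>(2 * c2 + 1) * H;
        size_t best = i00;
        if (x[i10] > x[best]) best = i10;
        if (x[i01] > x[best]) best = i01;
        if (x[i11] > x[best]) best = i11;
        const size_t o = r2 + static_cast<size_t>(c2) * H2;
        y[o] = x[best];
        wv[o] = best + 1;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y,
                            Rcpp::Named("which") = which);
}

// [[Rcpp::export(name = ".pool2_bwd")]]
arma::mat pool2_bwd(const arma::mat& dY, const arma::umat& which,
                    const int H, const int W) {
  const int C = dY.n_cols;
  mat dX(static_cast<uword>(H) * W, C, fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    double* d = dX.colptr(ch);
    const double* g = dY.colptr(ch);
    const uword* wv = which.colptr(ch);
    for (uword o = 0; o < dY.n_rows; ++o) d[wv[o] - 1] += g[o];
  }
  return dX;
}

struct LinW { int i0, i1; double w; };

// Per-axis source indices/weights for x2 bilinear upsampling with
// half-pixel centre alignment: output centre i maps to (i + 0.5)/2 - 0.5.
static std::vector<LinW> up2_weights(const int n) {
  std::vector<LinW> v(2 * n);
  for (int i = 0; i < 2 * n; ++i) {
    double u = (i + 0.5) / 2.0 - 0.5;
    if (u < 0) u = 0;
    if (u > n - 1) u = n - 1;
    const int i0 = static_cast<int>(std::floor(u));
    v[i].i0 = i0;
    v[i].i1 = std::min(i0 + 1, n - 1);
    v[i].w = u - i0;
  }
  return v;
}

// [[Rcpp::export(name = ".up2_fwd")]]
arma::mat up2_fwd(const arma::mat& X, const int H, const int W) {
  const int C = X.n_cols, H2 = 2 * H, W2 = 2 * W;
  const std::vector<LinW> rw = up2_weights(H), cw = up2_weights(W);
  mat Y(static_cast<uword>(H2) * W2, C);
  for (int ch = 0; ch < C; ++ch) {
    const double* x = X.colptr(ch);
    double* y = Y.colptr(ch);
    for (int c = 0; c < W2; ++c) {
      const LinW& cc = cw[c];
      for (int r = 0; r < H2; ++r) {
        const LinW& rr = rw[r];
        const double v00 = x[rr.i0 + static_cast<size_t>(cc.i0) * H];
        const double v10 = x[rr.i1 + static_cast<size_t>(cc.i0) * H];
        const double v01 = x[rr.i0 + static_cast<size_t>(cc.i1) * H];
        const double v11 = x[rr.i1 + static_cast<size_t>(cc.i1) * H];
        y[r + static_cast<size_t>(c) * H2] =
          (1 - rr.w) * (1 - cc.w) * v00 + rr.w * (1 - cc.w) * v10 +
          (1 - rr.w) * cc.w * v01 + rr.w * cc.w * v11;
      }
    }
  }
  return Y;
}

// [[Rcpp::export(name = ".up2_bwd")]]
arma::mat up2_bwd(const arma::mat& dY, const int H, const int W) {
  const int C = dY.n_cols, H2 = 2 * H, W2 = 2 * W;
  const std::vector<LinW> rw = up2_weights(H), cw = up2_weights(W);
  mat dX(static_cast<uword>(H) * W, C, fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    double* d = dX.colptr(ch);
    const double* g = dY.colptr(ch);
    for (int c = 0; c < W2; ++c) {
      const LinW& cc = cw[c];
      for (int r = 0; r < H2; ++r) {
        const LinW& rr = rw[r];
        const double gv = g[r + static_cast<size_t>(c) * H2];
        d[rr.i0 + static_cast<size_t>(cc.i0) * H] += (1 - rr.w) * (1 - cc.w) * gv;
        d[rr.i1 + static_cast<size_t>(cc.i0) * H] += rr.w * (1 - cc.w) * gv;
        d[rr.i0 + static_cast<size_t>(cc.i1) * H] += (1 - rr.w) * cc.w * gv;
        d[rr.i1 + static_cast<size_t>(cc.i1) * H] += rr.w * cc.w * gv;
      }
    }
  }
  return dX;
}
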