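// Dense kernels for the compact U-Net: 3x3 same-padding convolution
// (im2col + GEMM), 2x2 max pooling and nearest-neighbour 2x upsampling,
// each with its adjoint for backpropagation. Feature maps are H x W x C
// cubes; convolution weights are (9*Cin) x Cout matrices whose rows are
// ordered (dy, dx, channel) column-major to match the R-side reshape.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col3(const arma::cube& x) {
  const arma::uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat out(H * W, 9 * C);
  arma::uword k = 0;
  for (arma::uword c = 0; c < C; ++c) {
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        double* dst = out.colptr(k++);
        const arma::mat& sl = x.slice(c);
        for (arma::uword j = 0; j < W; ++j) {
          long sj = (long)j + dx;
          for (arma::uword i = 0; i < H; ++i) {
            long si = (long)i + dy;
            dst[i + j * H] =
              (si < 0 || sj < 0 || si >= (long)H || sj >= (long)W)
                ? 0.0 : sl((arma::uword)si, (arma::uword)sj);
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube conv3x3_fwd(const arma::cube& x, const arma::mat& w,
                       const arma::vec& b) {
  const arma::uword H = x.n_rows, W = x.n_cols;
  const arma::uword Cout = w.n_cols;
  arma::mat y = im2col3(x) * w;
  y.each_row() += b.t();
  arma::cube out(H, W, Cout);
  std::memcpy(out.memptr(), y.memptr(), sizeof(double) * y.n_elem);
  return out;
}

// [[Rcpp::export]]
List conv3x3_bwd(const arma::cube& x, const arma::mat& w,
                 const arma::cube& dout) {
  const arma::uword H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const arma::uword Cout = dout.n_slices;
  arma::mat dy((double*)dout.memptr(), H * W, Cout);
  arma::mat cols = im2col3(x);
  arma::mat dw = cols.t() * dy;
  arma::vec db = arma::sum(dy, 0).t();
  // dX: scatter dcols back (col2im), dcols = dy * w'
  arma::mat dcols = dy * w.t();
  arma::cube dx(H, W, Cin, arma::fill::zeros);
  arma::uword k = 0;
  for (arma::uword c = 0; c < Cin; ++c) {
    for (int dx_ = -1; dx_ <= 1; ++dx_) {
      for (int dy_ = -1; dy_ <= 1; ++dy_) {
        const double* src = dcols.colptr(k++);
        arma::mat& sl = dx.slice(c);
        for (arma::uword j = 0; j < W; ++j) {
          long sj = (long)j + dx_;
          if (sj < 0 || sj >= (long)W) continue;
          for (arma::uword i = 0; i < H; ++i) {
            long si = (long)i + dy_;
            if (si < 0 || si >= (long)H) continue;
            sl((arma::uword)si, (arma::uword)sj) += src[i + j * H];
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool2_fwd(const arma::cube& x) {
  const arma::uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const arma::uword h = H / 2, w = W / 2;
  arma::cube out(h, w, C);
  arma::ucube idx(h, w, C); // winner in 0..3: (dr, dc) = (idx%2, idx/2)
  for (arma::uword c = 0; c < C; ++c) {
    for (arma::uword j = 0; j < w; ++j) {
      for (arma::uword i = 0; i < h; ++i) {
        double best = x(2 * i, 2 * j, c);
        arma::uword bk = 0;
        const double cand1 = x(2 * i + 1, 2 * j, c);
        const double cand2 = x(2 * i, 2 * j + 1, c);
        const double cand3 = x(2 * i + 1, 2 * j + 1, c);
        if (cand1 > best) { best = cand1; bk = 1; }
        if (cand2 > best) { best = cand2; bk = 2; }
        if (cand3 > best) { best = cand3; bk = 3; }
        out(i, j, c) = best;
        idx(i, j, c) = bk;
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bwd(const arma::cube& dout, const arma::ucube& idx) {
  const arma::uword h = dout.n_rows, w = dout.n_cols, C = dout.n_slices;
  arma::cube dx(2 * h, 2 * w, C, arma::fill::zeros);
  for (arma::uword c = 0; c < C; ++c)
    for (arma::uword j = 0; j < w; ++j)
      for (arma::uword i = 0; i < h; ++i) {
        arma::uword k = idx(i, j, c);
        dx(2 * i + (k % 2), 2 * j + (k / 2), c) = dout(i, j, c);
      }
  return dx;
}

// [[Rcpp::export]]
arma::cube upsample2_fwd(const arma::cube& x) {
  const arma::uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube out(2 * H, 2 * W, C);
  for (arma::uword c = 0; c < C; ++c)
    for (arma::uword j = 0; j < 2 * W; ++j)
      for (arma::uword i = 0; i < 2 * H; ++i)
        out(i, j, c) = x(i / 2, j / 2, c);
  return out;
}

// [[Rcpp::export]]
arma::cube upsample2_bwd(const arma::cube& dout) {
  const arma::uword H = dout.n_rows / 2, W = dout.n_cols / 2,
                    C = dout.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (arma::uword c = 0; c < C; ++c)
    for (arma::uword j = 0; j < 2 * W; ++j)
      for (arma::uword i = 0; i < 2 * H; ++i)
        dx(i / 2, j / 2, c) += dout(i, j, c);
  return dx;
}
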