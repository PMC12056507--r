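// Low-level numeric kernels for the encoder-decoder segmenter:
// 3x3 same-padding convolution (im2col + GEMM), 2x2 max pooling and
// nearest-neighbour 2x upsampling, each with its adjoint for backprop.
// Layout: activations are H x W x C cubes; a 3x3 kernel bank is stored
// as a (C_in * 9) x C_out matrix whose row index is ch*9 + k with
// k = (dr+1) + (dc+1)*3 for offsets dr, dc in {-1, 0, 1}.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col3(const cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(H * (size_t)W, C * 9, fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    const mat& xs = x.slice(ch);
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const int k = (dr + 1) + (dc + 1) * 3;
        double* dst0 = out.colptr(ch * 9 + k);
        for (int c = 0; c < W; ++c) {
          const int cs = c + dc;
          if (cs < 0 || cs >= W) continue;
          const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
          if (r1 <= r0) continue;
          std::copy(xs.colptr(cs) + r0 + dr, xs.colptr(cs) + r1 + dr,
                    dst0 + (size_t)c * H + r0);
        }
      }
    }
  }
  return out;
}

static cube col2im3(const mat& colm, int H, int W, int C) {
  cube out(H, W, C, fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    mat& os = out.slice(ch);
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const int k = (dr + 1) + (dc + 1) * 3;
        const double* src0 = colm.colptr(ch * 9 + k);
        for (int c = 0; c < W; ++c) {
          const int cs = c + dc;
          if (cs < 0 || cs >= W) continue;
          const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
          double* dst = os.colptr(cs);
          const double* src = src0 + (size_t)c * H;
          for (int r = r0; r < r1; ++r) dst[r + dr] += src[r];
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube conv3_fw(const arma::cube& x, const arma::mat& w,
                    const arma::vec& b) {
  mat colm = im2col3(x);
  mat out = colm * w;
  out.each_row() += b.t();
  return cube(out.memptr(), x.n_rows, x.n_cols, w.n_cols);
}

// [[Rcpp::export]]
Rcpp::List conv3_bw(const arma::cube& x, const arma::mat& w,
                    const arma::cube& dout) {
  const int H = x.n_rows, W = x.n_cols;
  mat colm = im2col3(x);
  mat dom(const_cast<double*>(dout.memptr()), (size_t)H * W, dout.n_slices,
          false, true);
  mat dw = colm.t() * dom;
  vec db = sum(dom, 0).t();
  mat dcol = dom * w.t();
  cube dx = col2im3(dcol, H, W, x.n_slices);
  return Rcpp::List::create(Rcpp::Named("dw") = dw, Rcpp::Named("db") = db,
                            Rcpp::Named("dx") = dx);
}

// [[Rcpp::export]]
Rcpp::List maxpool2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube out(Ho, Wo, C);
  ucube arg(Ho, Wo, C);  // linear index within the input slice
  for (int ch = 0; ch < C; ++ch) {
    const mat& xs = x.slice(ch);
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        const int rr = 2 * r, cc = 2 * c;
        double best = xs(rr, cc);
        uword bi = rr + (size_t)cc * H;
        const int drs[4] = {0, 1, 0, 1}, dcs[4] = {0, 0, 1, 1};
        for (int q = 1; q < 4; ++q) {
          const double v = xs(rr + drs[q], cc + dcs[q]);
          if (v > best) {
            best = v;
            bi = (rr + drs[q]) + (size_t)(cc + dcs[q]) * H;
          }
        }
        out(r, c, ch) = best;
        arg(r, c, ch) = bi;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("arg") = arg);
}

// [[Rcpp::export]]
arma::cube maxpool2_bw(const arma::ucube& arg, const arma::cube& dout,
                       int H, int W) {
  const int C = dout.n_slices;
  cube dx(H, W, C, fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    double* dxs = dx.slice(ch).memptr();
    const mat& ds = dout.slice(ch);
    const umat& as = arg.slice(ch);
    for (uword i = 0; i < ds.n_elem; ++i) dxs[as(i)] += ds(i);
  }
  return dx;
}

// [[Rcpp::export]]
arma::cube upsample2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube out(2 * H, 2 * W, C);
  for (int ch = 0; ch < C; ++ch) {
    const mat& xs = x.slice(ch);
    mat& os = out.slice(ch);
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        const double v = xs(r, c);
        os(2 * r, 2 * c) = v;
        os(2 * r + 1, 2 * c) = v;
        os(2 * r, 2 * c + 1) = v;
        os(2 * r + 1, 2 * c + 1) = v;
      }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube upsample2_bw(const arma::cube& dout) {
  const int Ho = dout.n_rows / 2, Wo = dout.n_cols / 2, C = dout.n_slices;
  cube dx(Ho, Wo, C);
  for (int ch = 0; ch < C; ++ch) {
    const mat& ds = dout.slice(ch);
    mat& xs = dx.slice(ch);
    for (int c = 0; c < Wo; ++c)
      for (int r = 0; r < Ho; ++r)
        xs(r, c) = ds(2 * r, 2 * c) + ds(2 * r + 1, 2 * c) +
                   ds(2 * r, 2 * c + 1) + ds(2 * r + 1, 2 * c + 1);
  }
  return dx;
}
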