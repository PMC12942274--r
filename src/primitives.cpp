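#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Layout conventions (all 0-based internally):
//  - images / feature maps are R arrays dim (H, W, C), column-major;
//  - im2col rows enumerate output positions column-major (oy + Ho*ox);
//  - im2col columns enumerate (ki, kj, c) as ki + kh*kj + kh*kw*c, which
//    matches flattening a kernel array of dim (kh, kw, Cin, Cout).

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C,
                         int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericMatrix out(Ho * Wo, kh * kw * C);
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kh * kj + kh * kw * c;
        double* pout = &out(0, col);
        for (int ox = 0; ox < Wo; ++ox) {
          const int jx = ox * stride + kj - pad;
          for (int oy = 0; oy < Ho; ++oy) {
            const int iy = oy * stride + ki - pad;
            double v = 0.0;
            if (iy >= 0 && iy < H && jx >= 0 && jx < W)
              v = px[iy + H * jx + H * W * c];
            pout[oy + Ho * ox] = v;
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col: scatter-add columns back into an (H, W, C) array.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C,
                         int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericVector out(H * W * C);
  double* pout = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kh * kj + kh * kw * c;
        const double* pc = &cols(0, col);
        for (int ox = 0; ox < Wo; ++ox) {
          const int jx = ox * stride + kj - pad;
          if (jx < 0 || jx >= W) continue;
          for (int oy = 0; oy < Ho; ++oy) {
            const int iy = oy * stride + ki - pad;
            if (iy < 0 || iy >= H) continue;
            pout[iy + H * jx + H * W * c] += pc[oy + Ho * ox];
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C);
  return out;
}

// Connected-component labelling of a binary mask (4- or 8-connectivity).
// Components are numbered 1, 2, ... in row-major order of their first
// foreground pixel (scanning rows top to bottom, columns left to right).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int dy8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dy4[4] = {-1, 0, 0, 1};
  const int dx4[4] = {0, -1, 1, 0};
  const int ndir = (connectivity == 8) ? 8 : 4;
  const int* dy = (connectivity == 8) ? dy8 : dy4;
  const int* dx = (connectivity == 8) ? dx8 : dx4;
  int next = 0;
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      std::queue<std::pair<int, int> > q;
      q.push(std::make_pair(i, j));
      lab(i, j) = next;
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int d = 0; d < ndir; ++d) {
          const int ny = p.first + dy[d], nx = p.second + dx[d];
          if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
          if (mask(ny, nx) != 0 && lab(ny, nx) == 0) {
            lab(ny, nx) = next;
            q.push(std::make_pair(ny, nx));
          }
        }
      }
    }
  }
  return lab;
}
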