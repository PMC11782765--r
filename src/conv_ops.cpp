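#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Tensors are numeric arrays laid out channel-first (C, H, W, N),
// column-major, so a convolution output W %*% im2col(x) is already in
// layout (C_out, OH, OW, N) with no permutation.
// im2col column ordering: col = oy + OH*(ox + OW*n), row = ky + kh*(kx + kw*c).

static inline long at_chwn(int c, int y, int x, int n, int C, int H, int W) {
  return (long)c + (long)C * (y + (long)H * (x + (long)W * n));
}

// [[Rcpp::export]]
NumericMatrix im2col_cpp(const NumericVector& x, int H, int W, int C, int N,
                         int kh, int kw, int sh, int sw, int pt, int pl,
                         int OH, int OW) {
  NumericMatrix out(kh * kw * C, OH * OW * N);
  const double* px = x.begin();
  double* po = out.begin();
  const int nrow = kh * kw * C;
  for (int n = 0; n < N; ++n) {
    for (int ox = 0; ox < OW; ++ox) {
      for (int oy = 0; oy < OH; ++oy) {
        const long col = oy + (long)OH * (ox + (long)OW * n);
        double* dst = po + col * nrow;
        for (int kx = 0; kx < kw; ++kx) {
          const int xx = ox * sw - pl + kx;
          for (int ky = 0; ky < kh; ++ky) {
            const int yy = oy * sh - pt + ky;
            if (yy >= 0 && yy < H && xx >= 0 && xx < W) {
              const double* src = px + at_chwn(0, yy, xx, n, C, H, W);
              for (int c = 0; c < C; ++c)
                dst[ky + kh * (kx + kw * c)] = src[c];
            } else {
              for (int c = 0; c < C; ++c)
                dst[ky + kh * (kx + kw * c)] = 0.0;
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(const NumericMatrix& cols, int H, int W, int C, int N,
                         int kh, int kw, int sh, int sw, int pt, int pl,
                         int OH, int OW) {
  NumericVector out((long)H * W * C * N);
  double* po = out.begin();
  const double* pc = cols.begin();
  const int nrow = kh * kw * C;
  for (int n = 0; n < N; ++n) {
    for (int ox = 0; ox < OW; ++ox) {
      for (int oy = 0; oy < OH; ++oy) {
        const long col = oy + (long)OH * (ox + (long)OW * n);
        const double* src = pc + col * nrow;
        for (int kx = 0; kx < kw; ++kx) {
          const int xx = ox * sw - pl + kx;
          if (xx < 0 || xx >= W) continue;
          for (int ky = 0; ky < kh; ++ky) {
            const int yy = oy * sh - pt + ky;
            if (yy < 0 || yy >= H) continue;
            double* dst = po + at_chwn(0, yy, xx, n, C, H, W);
            for (int c = 0; c < C; ++c)
              dst[c] += src[ky + kh * (kx + kw * c)];
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(C, H, W, N);
  return out;
}

// Max pooling; padded cells never win (window always overlaps the image when
// pads < window). Returns output and 1-based argmax indices into x.
// [[Rcpp::export]]
List maxpool_cpp(const NumericVector& x, int H, int W, int C, int N,
                 int kh, int kw, int sh, int sw, int pt, int pl,
                 int OH, int OW) {
  NumericVector out((long)OH * OW * C * N);
  IntegerVector idx((long)OH * OW * C * N);
  const double* px = x.begin();
  for (int n = 0; n < N; ++n)
    for (int ox = 0; ox < OW; ++ox)
      for (int oy = 0; oy < OH; ++oy) {
        const long obase = (long)C * (oy + (long)OH * (ox + (long)OW * n));
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf; long bi = -1;
          for (int kx = 0; kx < kw; ++kx) {
            const int xx = ox * sw - pl + kx;
            if (xx < 0 || xx >= W) continue;
            for (int ky = 0; ky < kh; ++ky) {
              const int yy = oy * sh - pt + ky;
              if (yy < 0 || yy >= H) continue;
              const long ii = at_chwn(c, yy, xx, n, C, H, W);
              if (px[ii] > best) { best = px[ii]; bi = ii; }
            }
          }
          out[obase + c] = best; idx[obase + c] = (int)(bi + 1);
        }
      }
  out.attr("dim") = IntegerVector::create(C, OH, OW, N);
  idx.attr("dim") = IntegerVector::create(C, OH, OW, N);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(const NumericVector& dout, const IntegerVector& idx,
                              int H, int W, int C, int N) {
  NumericVector dx((long)H * W * C * N);
  for (long i = 0; i < dout.size(); ++i) dx[idx[i] - 1] += dout[i];
  dx.attr("dim") = IntegerVector::create(C, H, W, N);
  return dx;
}

// Average pooling over the valid (non-padded) part of each window.
// [[Rcpp::export]]
List avgpool_cpp(const NumericVector& x, int H, int W, int C, int N,
                 int kh, int kw, int sh, int sw, int pt, int pl,
                 int OH, int OW) {
  NumericVector out((long)OH * OW * C * N);
  IntegerVector cnt((long)OH * OW * C * N);
  const double* px = x.begin();
  for (int n = 0; n < N; ++n)
    for (int ox = 0; ox < OW; ++ox)
      for (int oy = 0; oy < OH; ++oy) {
        const long obase = (long)C * (oy + (long)OH * (ox + (long)OW * n));
        int m = 0;
        for (int kx = 0; kx < kw; ++kx) {
          const int xx = ox * sw - pl + kx;
          if (xx < 0 || xx >= W) continue;
          for (int ky = 0; ky < kh; ++ky) {
            const int yy = oy * sh - pt + ky;
            if (yy < 0 || yy >= H) continue;
            ++m;
            const double* src = px + at_chwn(0, yy, xx, n, C, H, W);
            for (int c = 0; c < C; ++c) out[obase + c] += src[c];
          }
        }
        for (int c = 0; c < C; ++c) { out[obase + c] /= m; cnt[obase + c] = m; }
      }
  out.attr("dim") = IntegerVector::create(C, OH, OW, N);
  cnt.attr("dim") = IntegerVector::create(C, OH, OW, N);
  return List::create(_["out"] = out, _["cnt"] = cnt);
}

// [[Rcpp::export]]
NumericVector avgpool_bwd_cpp(const NumericVector& dout, const IntegerVector& cnt,
                              int H, int W, int C, int N,
                              int kh, int kw, int sh, int sw, int pt, int pl,
                              int OH, int OW) {
  NumericVector dx((long)H * W * C * N);
  for (int n = 0; n < N; ++n)
    for (int ox = 0; ox < OW; ++ox)
      for (int oy = 0; oy < OH; ++oy) {
        const long obase = (long)C * (oy + (long)OH * (ox + (long)OW * n));
        for (int kx = 0; kx < kw; ++kx) {
          const int xx = ox * sw - pl + kx;
          if (xx < 0 || xx >= W) continue;
          for (int ky = 0; ky < kh; ++ky) {
            const int yy = oy * sh - pt + ky;
            if (yy < 0 || yy >= H) continue;
            double* dst = dx.begin() + at_chwn(0, yy, xx, n, C, H, W);
            for (int c = 0; c < C; ++c)
              dst[c] += dout[obase + c] / cnt[obase + c];
          }
        }
      }
  dx.attr("dim") = IntegerVector::create(C, H, W, N);
  return dx;
}

// Grayscale square-kernel minimum filter with edge replication.
// [[Rcpp::export]]
NumericMatrix minfilt_cpp(const NumericMatrix& img, int k) {
  const int H = img.nrow(), W = img.ncol(), r = k / 2;
  NumericMatrix out(H, W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      double best = R_PosInf;
      for (int dx = -r; dx <= r; ++dx) {
        int xx = std::min(std::max(x + dx, 0), W - 1);
        for (int dy = -r; dy <= r; ++dy) {
          int yy = std::min(std::max(y + dy, 0), H - 1);
          best = std::min(best, img(yy, xx));
        }
      }
      out(y, x) = best;
    }
  return out;
}

// Grayscale square-window median filter with edge replication.
// [[Rcpp::export]]
NumericMatrix medfilt_cpp(const NumericMatrix& img, int k) {
  const int H = img.nrow(), W = img.ncol(), r = k / 2;
  NumericMatrix out(H, W);
  std::vector<double> buf(k * k);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      int m = 0;
      for (int dx = -r; dx <= r; ++dx) {
        int xx = std::min(std::max(x + dx, 0), W - 1);
        for (int dy = -r; dy <= r; ++dy) {
          int yy = std::min(std::max(y + dy, 0), H - 1);
          buf[m++] = img(yy, xx);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
      out(y, x) = buf[m / 2];
    }
  return out;
}

// Bilinear resize (half-pixel centers, clamped) of an H x W x C array
// (channel-last; used only for plain images, not network tensors).
// [[Rcpp::export]]
NumericVector resize_bilinear_cpp(const NumericVector& x, int H, int W, int C,
                                  int oh, int ow) {
  NumericVector out((long)oh * ow * C);
  const double sy = (double)H / oh, sx = (double)W / ow;
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* plane = px + (long)c * H * W;
    double* po = out.begin() + (long)c * oh * ow;
    for (int j = 0; j < ow; ++j) {
      double fx = (j + 0.5) * sx - 0.5;
      int x0 = (int)std::floor(fx);
      double wx = fx - x0;
      int x0c = std::min(std::max(x0, 0), W - 1);
      int x1c = std::min(std::max(x0 + 1, 0), W - 1);
      for (int i = 0; i < oh; ++i) {
        double fy = (i + 0.5) * sy - 0.5;
        int y0 = (int)std::floor(fy);
        double wy = fy - y0;
        int y0c = std::min(std::max(y0, 0), H - 1);
        int y1c = std::min(std::max(y0 + 1, 0), H - 1);
        double v00 = plane[y0c + (long)H * x0c], v01 = plane[y0c + (long)H * x1c];
        double v10 = plane[y1c + (long)H * x0c], v11 = plane[y1c + (long)H * x1c];
        po[i + (long)oh * j] = (1 - wy) * ((1 - wx) * v00 + wx * v01) +
                               wy * ((1 - wx) * v10 + wx * v11);
      }
    }
  }
  out.attr("dim") = IntegerVector::create(oh, ow, C);
  return out;
}
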