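// Compute kernels for the neural-network layers.
// Tensor layout throughout: R numeric arrays, column-major, dim = (H, W, C, B).
// Conv weights: dim = (kh, kw, Cin, Cout); depthwise weights: (kh, kw, C).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad, int dil) {
  int eff = dil * (k - 1) + 1;
  return (n + 2 * pad - eff) / stride + 1;
}

// Fill `cols` ((kh*kw*Cin) x (Ho*Wo)) from one image slice of x.
static void im2col_one(const double* x, int H, int W, int C,
                       int kh, int kw, int stride, int pad, int dil,
                       int Ho, int Wo, arma::mat& cols) {
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      int col = oh + Ho * ow;
      double* dst = cols.colptr(col);
      for (int c = 0; c < C; ++c) {
        const double* xc = x + (size_t)H * W * c;
        for (int j = 0; j < kw; ++j) {
          int iw = ow * stride - pad + j * dil;
          for (int i = 0; i < kh; ++i) {
            int ih = oh * stride - pad + i * dil;
            double v = 0.0;
            if (ih >= 0 && ih < H && iw >= 0 && iw < W)
              v = xc[ih + (size_t)H * iw];
            dst[i + kh * (j + kw * c)] = v;
          }
        }
      }
    }
  }
}

// Scatter-add `cols` back into one image slice of dx.
static void col2im_one(const arma::mat& cols, int H, int W, int C,
                       int kh, int kw, int stride, int pad, int dil,
                       int Ho, int Wo, double* dx) {
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      int col = oh + Ho * ow;
      const double* src = cols.colptr(col);
      for (int c = 0; c < C; ++c) {
        double* dc = dx + (size_t)H * W * c;
        for (int j = 0; j < kw; ++j) {
          int iw = ow * stride - pad + j * dil;
          if (iw < 0 || iw >= W) continue;
          for (int i = 0; i < kh; ++i) {
            int ih = oh * stride - pad + i * dil;
            if (ih < 0 || ih >= H) continue;
            dc[ih + (size_t)H * iw] += src[i + kh * (j + kw * c)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch in conv2d");
  int Ho = out_size(H, kh, stride, pad, dil);
  int Wo = out_size(W, kw, stride, pad, dil);
  if (Ho <= 0 || Wo <= 0) stop("conv2d output would be empty");
  NumericVector y(Ho * Wo * (size_t)Cout * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, B);
  arma::mat Wm(w.begin(), kh * kw * Cin, Cout, false, true);
  arma::mat cols(kh * kw * Cin, Ho * Wo);
  for (int img = 0; img < B; ++img) {
    const double* xi = x.begin() + (size_t)H * W * C * img;
    im2col_one(xi, H, W, C, kh, kw, stride, pad, dil, Ho, Wo, cols);
    arma::mat outT = cols.t() * Wm;  // (Ho*Wo) x Cout
    double* yi = y.begin() + (size_t)Ho * Wo * Cout * img;
    for (int c = 0; c < Cout; ++c) {
      double bc = b[c];
      const double* oc = outT.colptr(c);
      double* yc = yi + (size_t)Ho * Wo * c;
      for (int p = 0; p < Ho * Wo; ++p) yc[p] = oc[p] + bc;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd")]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  NumericVector dx(x.size()); dx.attr("dim") = xd;
  NumericVector dw(w.size()); dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat Wm(w.begin(), kh * kw * Cin, Cout, false, true);
  arma::mat dWm(dw.begin(), kh * kw * Cin, Cout, false, true);
  arma::mat cols(kh * kw * Cin, Ho * Wo);
  for (int img = 0; img < B; ++img) {
    const double* xi = x.begin() + (size_t)H * W * C * img;
    im2col_one(xi, H, W, C, kh, kw, stride, pad, dil, Ho, Wo, cols);
    arma::mat dyT(const_cast<double*>(dy.begin()) + (size_t)Ho * Wo * Cout * img,
                  Ho * Wo, Cout, false, true);
    dWm += cols * dyT;
    for (int c = 0; c < Cout; ++c) db[c] += arma::accu(dyT.col(c));
    arma::mat dcols = Wm * dyT.t();  // (kh*kw*Cin) x (Ho*Wo)
    col2im_one(dcols, H, W, C, kh, kw, stride, pad, dil, Ho, Wo,
               dx.begin() + (size_t)H * W * C * img);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".cpp_dwconv2d_fwd")]]
NumericVector cpp_dwconv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                               int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int kh = wd[0], kw = wd[1];
  int Ho = out_size(H, kh, stride, pad, 1);
  int Wo = out_size(W, kw, stride, pad, 1);
  NumericVector y(Ho * Wo * (size_t)C * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  for (int img = 0; img < B; ++img) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * img);
      const double* wc = w.begin() + (size_t)kh * kw * c;
      double* yc = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * img);
      for (int ow = 0; ow < Wo; ++ow) {
        for (int oh = 0; oh < Ho; ++oh) {
          double acc = b[c];
          for (int j = 0; j < kw; ++j) {
            int iw = ow * stride - pad + j;
            if (iw < 0 || iw >= W) continue;
            for (int i = 0; i < kh; ++i) {
              int ih = oh * stride - pad + i;
              if (ih < 0 || ih >= H) continue;
              acc += xc[ih + (size_t)H * iw] * wc[i + kh * j];
            }
          }
          yc[oh + (size_t)Ho * ow] = acc;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_dwconv2d_bwd")]]
List cpp_dwconv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                      int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int kh = wd[0], kw = wd[1];
  int Ho = yd[0], Wo = yd[1];
  NumericVector dx(x.size()); dx.attr("dim") = xd;
  NumericVector dw(w.size()); dw.attr("dim") = wd;
  NumericVector db(C);
  for (int img = 0; img < B; ++img) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * img);
      const double* wc = w.begin() + (size_t)kh * kw * c;
      const double* gc = dy.begin() + (size_t)Ho * Wo * (c + (size_t)C * img);
      double* dxc = dx.begin() + (size_t)H * W * (c + (size_t)C * img);
      double* dwc = dw.begin() + (size_t)kh * kw * c;
      for (int ow = 0; ow < Wo; ++ow) {
        for (int oh = 0; oh < Ho; ++oh) {
          double g = gc[oh + (size_t)Ho * ow];
          db[c] += g;
          for (int j = 0; j < kw; ++j) {
            int iw = ow * stride - pad + j;
            if (iw < 0 || iw >= W) continue;
            for (int i = 0; i < kh; ++i) {
              int ih = oh * stride - pad + i;
              if (ih < 0 || ih >= H) continue;
              dwc[i + kh * j] += g * xc[ih + (size_t)H * iw];
              dxc[ih + (size_t)H * iw] += g * wc[i + kh * j];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

struct BilinWeights {
  std::vector<int> i0, i1;
  std::vector<double> w0, w1;
};

static BilinWeights bilin_axis(int n_out, int n_in) {
  BilinWeights bw;
  bw.i0.resize(n_out); bw.i1.resize(n_out);
  bw.w0.resize(n_out); bw.w1.resize(n_out);
  double scale = (double)n_in / n_out;
  for (int o = 0; o < n_out; ++o) {
    double src = (o + 0.5) * scale - 0.5;
    if (src < 0) src = 0;
    if (src > n_in - 1) src = n_in - 1;
    int i0 = (int)std::floor(src);
    int i1 = std::min(i0 + 1, n_in - 1);
    double f = src - i0;
    bw.i0[o] = i0; bw.i1[o] = i1; bw.w0[o] = 1.0 - f; bw.w1[o] = f;
  }
  return bw;
}

// [[Rcpp::export(name = ".cpp_resize_bilinear_fwd")]]
NumericVector cpp_resize_bilinear_fwd(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  NumericVector y((size_t)Ho * Wo * C * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  BilinWeights rh = bilin_axis(Ho, H), rw = bilin_axis(Wo, W);
  for (int s = 0; s < C * B; ++s) {
    const double* xs = x.begin() + (size_t)H * W * s;
    double* ys = y.begin() + (size_t)Ho * Wo * s;
    for (int ow = 0; ow < Wo; ++ow) {
      int w0 = rw.i0[ow], w1 = rw.i1[ow];
      double fw0 = rw.w0[ow], fw1 = rw.w1[ow];
      for (int oh = 0; oh < Ho; ++oh) {
        int h0 = rh.i0[oh], h1 = rh.i1[oh];
        ys[oh + (size_t)Ho * ow] =
          rh.w0[oh] * (fw0 * xs[h0 + (size_t)H * w0] + fw1 * xs[h0 + (size_t)H * w1]) +
          rh.w1[oh] * (fw0 * xs[h1 + (size_t)H * w0] + fw1 * xs[h1 + (size_t)H * w1]);
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_resize_bilinear_bwd")]]
NumericVector cpp_resize_bilinear_bwd(NumericVector dy, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], B = yd[3];
  NumericVector dx((size_t)H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  BilinWeights rh = bilin_axis(Ho, H), rw = bilin_axis(Wo, W);
  for (int s = 0; s < C * B; ++s) {
    const double* gs = dy.begin() + (size_t)Ho * Wo * s;
    double* ds = dx.begin() + (size_t)H * W * s;
    for (int ow = 0; ow < Wo; ++ow) {
      int w0 = rw.i0[ow], w1 = rw.i1[ow];
      double fw0 = rw.w0[ow], fw1 = rw.w1[ow];
      for (int oh = 0; oh < Ho; ++oh) {
        double g = gs[oh + (size_t)Ho * ow];
        int h0 = rh.i0[oh], h1 = rh.i1[oh];
        ds[h0 + (size_t)H * w0] += rh.w0[oh] * fw0 * g;
        ds[h0 + (size_t)H * w1] += rh.w0[oh] * fw1 * g;
        ds[h1 + (size_t)H * w0] += rh.w1[oh] * fw0 * g;
        ds[h1 + (size_t)H * w1] += rh.w1[oh] * fw1 * g;
      }
    }
  }
  return dx;
}
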