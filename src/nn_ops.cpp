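// Convolution and pooling kernels for the CPU network engine.
// Tensor layout throughout: column-major R arrays [H, W, C, N];
// convolution weights [kh, kw, C_in/groups, C_out].
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::mat;

static inline void get_dims4(const NumericVector& x, int* d) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d tensor [H, W, C, N]");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// Unfold one group's channels of one sample into a (kh*kw*Cg) x (Ho*Wo)
// patch matrix; rows ordered i (kernel row) fastest, then j, then channel,
// matching the column-major flattening of the weight tensor.
static void im2col(const double* xg, int H, int W, int Cg,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, mat& cols) {
  for (int c = 0; c < Cg; ++c) {
    const double* plane = xg + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int r = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int win = wo * stride - pad + j;
          bool wok = (win >= 0 && win < W);
          for (int ho = 0; ho < Ho; ++ho) {
            int hin = ho * stride - pad + i;
            double v = 0.0;
            if (wok && hin >= 0 && hin < H)
              v = plane[hin + (size_t)H * win];
            cols(r, ho + (size_t)Ho * wo) = v;
          }
        }
      }
    }
  }
}

static void col2im(const mat& cols, double* dxg, int H, int W, int Cg,
                   int kh, int kw, int stride, int pad, int Ho, int Wo) {
  for (int c = 0; c < Cg; ++c) {
    double* plane = dxg + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int r = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int win = wo * stride - pad + j;
          if (win < 0 || win >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hin = ho * stride - pad + i;
            if (hin < 0 || hin >= H) continue;
            plane[hin + (size_t)H * win] += cols(r, ho + (size_t)Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 NumericVector b, int stride, int pad,
                                 int groups) {
  int xd[4]; get_dims4(x, xd);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  IntegerVector wd = w.attr("dim");
  int kh = wd[0], kw = wd[1], Cg = wd[2], Cout = wd[3];
  if (C != Cg * groups) stop("input channels inconsistent with weight/groups");
  if (Cout % groups != 0) stop("output channels not divisible by groups");
  int Cog = Cout / groups;
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded input");

  size_t P = (size_t)Ho * Wo, R = (size_t)kh * kw * Cg;
  NumericVector y(P * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  mat Wm(const_cast<double*>(w.begin()), R, Cout, false, true);
  mat cols(R, P);

  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      const double* xg = x.begin() + (size_t)H * W * (g * Cg + (size_t)C * n);
      im2col(xg, H, W, Cg, kh, kw, stride, pad, Ho, Wo, cols);
      mat Yt = cols.t() * Wm.cols(g * Cog, (g + 1) * Cog - 1); // P x Cog
      for (int o = 0; o < Cog; ++o) {
        double* yp = y.begin() + P * (g * Cog + o + (size_t)Cout * n);
        double bo = b[g * Cog + o];
        const double* src = Yt.colptr(o);
        for (size_t p = 0; p < P; ++p) yp[p] = src[p] + bo;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                         int stride, int pad, int groups) {
  int xd[4]; get_dims4(x, xd);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  IntegerVector wd = w.attr("dim");
  int kh = wd[0], kw = wd[1], Cg = wd[2], Cout = wd[3];
  int Cog = Cout / groups;
  int yd[4]; get_dims4(dy, yd);
  int Ho = yd[0], Wo = yd[1];
  size_t P = (size_t)Ho * Wo, R = (size_t)kh * kw * Cg;

  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  NumericVector dw(w.size());
  dw.attr("dim") = w.attr("dim");
  NumericVector db(Cout);
  mat Wm(const_cast<double*>(w.begin()), R, Cout, false, true);
  mat dWm(dw.begin(), R, Cout, false, true);
  mat cols(R, P);

  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      const double* xg = x.begin() + (size_t)H * W * (g * Cg + (size_t)C * n);
      im2col(xg, H, W, Cg, kh, kw, stride, pad, Ho, Wo, cols);
      // dy planes of this group's channels are contiguous: view as P x Cog
      mat Dg(const_cast<double*>(dy.begin()) +
                 P * (g * (size_t)Cog + (size_t)Cout * n),
             P, Cog, false, true);
      dWm.cols(g * Cog, (g + 1) * Cog - 1) += cols * Dg;
      for (int o = 0; o < Cog; ++o) db[g * Cog + o] += arma::accu(Dg.col(o));
      mat dcols = Wm.cols(g * Cog, (g + 1) * Cog - 1) * Dg.t(); // R x P
      double* dxg = dx.begin() + (size_t)H * W * (g * Cg + (size_t)C * n);
      col2im(dcols, dxg, H, W, Cg, kh, kw, stride, pad, Ho, Wo);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector x, int k, int stride, int pad) {
  int xd[4]; get_dims4(x, xd);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  size_t P = (size_t)Ho * Wo;
  NumericVector y(P * C * N);
  IntegerVector idx(P * C * N);
  y.attr("dim") = idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);

  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* plane = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yp = y.begin() + P * (c + (size_t)C * n);
      int* ip = idx.begin() + P * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -INFINITY; int bidx = -1;
          for (int j = 0; j < k; ++j) {
            int win = wo * stride - pad + j;
            if (win < 0 || win >= W) continue;
            for (int i = 0; i < k; ++i) {
              int hin = ho * stride - pad + i;
              if (hin < 0 || hin >= H) continue;
              double v = plane[hin + (size_t)H * win];
              if (v > best) { best = v; bidx = hin + H * win; }
            }
          }
          yp[ho + (size_t)Ho * wo] = best;
          ip[ho + (size_t)Ho * wo] = bidx;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(IntegerVector idx, IntegerVector in_dim,
                                   NumericVector dy) {
  int H = in_dim[0], W = in_dim[1], C = in_dim[2], N = in_dim[3];
  int yd[4]; get_dims4(dy, yd);
  size_t P = (size_t)yd[0] * yd[1];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = in_dim;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      size_t off = P * (c + (size_t)C * n);
      double* dplane = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (size_t p = 0; p < P; ++p) {
        int b = idx[off + p];
        if (b >= 0) dplane[b] += dy[off + p];
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_forward(NumericVector x, int k, int stride) {
  int xd[4]; get_dims4(x, xd);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = (H - k) / stride + 1, Wo = (W - k) / stride + 1;
  size_t P = (size_t)Ho * Wo;
  NumericVector y(P * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  double inv = 1.0 / (k * k);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* plane = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yp = y.begin() + P * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double s = 0.0;
          for (int j = 0; j < k; ++j)
            for (int i = 0; i < k; ++i)
              s += plane[(ho * stride + i) + (size_t)H * (wo * stride + j)];
          yp[ho + (size_t)Ho * wo] = s * inv;
        }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_backward(IntegerVector in_dim, NumericVector dy,
                                   int k, int stride) {
  int H = in_dim[0], W = in_dim[1], C = in_dim[2], N = in_dim[3];
  int yd[4]; get_dims4(dy, yd);
  int Ho = yd[0], Wo = yd[1];
  size_t P = (size_t)Ho * Wo;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = in_dim;
  double inv = 1.0 / (k * k);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* dplane = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* dyp = dy.begin() + P * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double g = dyp[ho + (size_t)Ho * wo] * inv;
          for (int j = 0; j < k; ++j)
            for (int i = 0; i < k; ++i)
              dplane[(ho * stride + i) + (size_t)H * (wo * stride + j)] += g;
        }
    }
  }
  return dx;
}
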