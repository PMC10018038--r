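// Low-level tensor kernels for the network engine.
//
// Feature blocks are R arrays with dim (H, W, C, N): height index fastest,
// matching R's column-major layout. Convolutions go through im2col + GEMM
// (Armadillo/BLAS); depthwise and geometric ops are direct loops.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Fill column matrix (k*k*Cin x Ho*Wo) for one sample. Row index layout:
// i1 + k*i2 + k*k*ci  (i1 = kernel row, i2 = kernel col, ci = input channel);
// column index: ho + Ho*wo.
static void im2col(const double* x, int H, int W, int C,
                   int k, int stride, int pad, arma::mat& col) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  col.zeros(k * k * C, Ho * Wo);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      double* dst = col.colptr(ho + Ho * wo);
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      for (int ci = 0; ci < C; ++ci) {
        const double* xc = x + (size_t)H * W * ci;
        for (int i2 = 0; i2 < k; ++i2) {
          const int w = w0 + i2;
          if (w < 0 || w >= W) continue;
          for (int i1 = 0; i1 < k; ++i1) {
            const int h = h0 + i1;
            if (h < 0 || h >= H) continue;
            dst[i1 + k * i2 + k * k * ci] = xc[h + (size_t)H * w];
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& col, int H, int W, int C,
                   int k, int stride, int pad, double* dx) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double* src = col.colptr(ho + Ho * wo);
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      for (int ci = 0; ci < C; ++ci) {
        double* xc = dx + (size_t)H * W * ci;
        for (int i2 = 0; i2 < k; ++i2) {
          const int w = w0 + i2;
          if (w < 0 || w >= W) continue;
          for (int i1 = 0; i1 < k; ++i1) {
            const int h = h0 + i1;
            if (h < 0 || h >= H) continue;
            xc[h + (size_t)H * w] += src[i1 + k * i2 + k * k * ci];
          }
        }
      }
    }
  }
}

// x: (H,W,Cin,N); w: (k,k,Cin,Cout) flattened column-major; b: Cout.
// [[Rcpp::export(name = ".conv2d_forward")]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector w,
                                 NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[1] != k || wd[2] != C) stop("conv2d: weight/input channel mismatch");
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv2d: output size would be empty");

  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * C, Cout, false, true);
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  arma::mat col;
  const bool is1x1 = (k == 1 && stride == 1 && pad == 0);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    double* yn = y.begin() + (size_t)Ho * Wo * Cout * n;
    arma::mat Yn(yn, (size_t)Ho * Wo, Cout, false, true);
    if (is1x1) {
      // 1x1 conv: feature block is already the column matrix (HW x C)
      arma::mat Xn(const_cast<double*>(xn), (size_t)H * W, C, false, true);
      Yn = Xn * Wm;
    } else {
      im2col(xn, H, W, C, k, stride, pad, col);
      Yn = col.t() * Wm;
    }
    for (int co = 0; co < Cout; ++co) Yn.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_backward")]]
List conv2d_backward_cpp(NumericVector x, NumericVector w, NumericVector dy,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];

  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * C, Cout, false, true);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat dWm(dw.begin(), (size_t)k * k * C, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);

  arma::mat col;
  const bool is1x1 = (k == 1 && stride == 1 && pad == 0);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    double* dyn = const_cast<double*>(dy.begin()) + (size_t)Ho * Wo * Cout * n;
    arma::mat dYn(dyn, (size_t)Ho * Wo, Cout, false, true);
    dbv += arma::sum(dYn, 0).t();
    if (is1x1) {
      arma::mat Xn(const_cast<double*>(xn), (size_t)H * W, C, false, true);
      dWm += Xn.t() * dYn;
      double* dxn = dx.begin() + (size_t)H * W * C * n;
      arma::mat dXn(dxn, (size_t)H * W, C, false, true);
      dXn = dYn * Wm.t();
    } else {
      im2col(xn, H, W, C, k, stride, pad, col);
      dWm += col * dYn;
      arma::mat dcol = Wm * dYn.t();  // (kkC x HoWo)
      col2im(dcol, H, W, C, k, stride, pad,
             dx.begin() + (size_t)H * W * C * n);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Depthwise conv, stride 1, zero pad. w: (k,k,C), b: C.
// [[Rcpp::export(name = ".dwconv_forward")]]
NumericVector dwconv_forward_cpp(NumericVector x, NumericVector w,
                                 NumericVector b, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0];
  if (wd[2] != C) stop("dwconv: channel mismatch");
  const int Ho = out_size(H, k, 1, pad);
  const int Wo = out_size(W, k, 1, pad);

  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* wc = w.begin() + (size_t)k * k * c;
      double* yc = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = b[c];
          const int h0 = ho - pad, w0 = wo - pad;
          for (int i2 = 0; i2 < k; ++i2) {
            const int ww = w0 + i2;
            if (ww < 0 || ww >= W) continue;
            for (int i1 = 0; i1 < k; ++i1) {
              const int hh = h0 + i1;
              if (hh < 0 || hh >= H) continue;
              acc += xc[hh + (size_t)H * ww] * wc[i1 + k * i2];
            }
          }
          yc[ho + (size_t)Ho * wo] = acc;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".dwconv_backward")]]
List dwconv_backward_cpp(NumericVector x, NumericVector w, NumericVector dy,
                         int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0];
  const int Ho = yd[0], Wo = yd[1];

  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(C);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* wc = w.begin() + (size_t)k * k * c;
      const double* dyc = dy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      double* dxc = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* dwc = dw.begin() + (size_t)k * k * c;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const double g = dyc[ho + (size_t)Ho * wo];
          if (g == 0.0) continue;
          db[c] += g;
          const int h0 = ho - pad, w0 = wo - pad;
          for (int i2 = 0; i2 < k; ++i2) {
            const int ww = w0 + i2;
            if (ww < 0 || ww >= W) continue;
            for (int i1 = 0; i1 < k; ++i1) {
              const int hh = h0 + i1;
              if (hh < 0 || hh >= H) continue;
              dwc[i1 + k * i2] += g * xc[hh + (size_t)H * ww];
              dxc[hh + (size_t)H * ww] += g * wc[i1 + k * i2];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Bilinear upsampling by integer factor. Source coordinate of output pixel o
// is (o + 0.5)/f - 0.5, clamped to the valid range (half-pixel centers).
// [[Rcpp::export(name = ".upsample_forward")]]
NumericVector upsample_forward_cpp(NumericVector x, int factor) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H * factor, Wo = W * factor;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);

  std::vector<int> i0(Ho), i1v(Ho), j0(Wo), j1v(Wo);
  std::vector<double> ai(Ho), aj(Wo);
  for (int o = 0; o < Ho; ++o) {
    double s = (o + 0.5) / factor - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    i0[o] = (int)std::floor(s);
    i1v[o] = std::min(i0[o] + 1, H - 1);
    ai[o] = s - i0[o];
  }
  for (int o = 0; o < Wo; ++o) {
    double s = (o + 0.5) / factor - 0.5;
    if (s < 0) s = 0;
    if (s > W - 1) s = W - 1;
    j0[o] = (int)std::floor(s);
    j1v[o] = std::min(j0[o] + 1, W - 1);
    aj[o] = s - j0[o];
  }
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xc = x.begin() + (size_t)H * W * cn;
    double* yc = y.begin() + (size_t)Ho * Wo * cn;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const double v00 = xc[i0[ho] + (size_t)H * j0[wo]];
        const double v10 = xc[i1v[ho] + (size_t)H * j0[wo]];
        const double v01 = xc[i0[ho] + (size_t)H * j1v[wo]];
        const double v11 = xc[i1v[ho] + (size_t)H * j1v[wo]];
        yc[ho + (size_t)Ho * wo] =
          (1 - ai[ho]) * ((1 - aj[wo]) * v00 + aj[wo] * v01) +
          ai[ho] * ((1 - aj[wo]) * v10 + aj[wo] * v11);
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".upsample_backward")]]
NumericVector upsample_backward_cpp(NumericVector dy, int factor,
                                    int Hin, int Win) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx((size_t)Hin * Win * C * N);
  dx.attr("dim") = IntegerVector::create(Hin, Win, C, N);

  std::vector<int> i0(Ho), i1v(Ho), j0(Wo), j1v(Wo);
  std::vector<double> ai(Ho), aj(Wo);
  for (int o = 0; o < Ho; ++o) {
    double s = (o + 0.5) / factor - 0.5;
    if (s < 0) s = 0;
    if (s > Hin - 1) s = Hin - 1;
    i0[o] = (int)std::floor(s);
    i1v[o] = std::min(i0[o] + 1, Hin - 1);
    ai[o] = s - i0[o];
  }
  for (int o = 0; o < Wo; ++o) {
    double s = (o + 0.5) / factor - 0.5;
    if (s < 0) s = 0;
    if (s > Win - 1) s = Win - 1;
    j0[o] = (int)std::floor(s);
    j1v[o] = std::min(j0[o] + 1, Win - 1);
    aj[o] = s - j0[o];
  }
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* dyc = dy.begin() + (size_t)Ho * Wo * cn;
    double* dxc = dx.begin() + (size_t)Hin * Win * cn;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const double g = dyc[ho + (size_t)Ho * wo];
        dxc[i0[ho] + (size_t)Hin * j0[wo]] += (1 - ai[ho]) * (1 - aj[wo]) * g;
        dxc[i1v[ho] + (size_t)Hin * j0[wo]] += ai[ho] * (1 - aj[wo]) * g;
        dxc[i0[ho] + (size_t)Hin * j1v[wo]] += (1 - ai[ho]) * aj[wo] * g;
        dxc[i1v[ho] + (size_t)Hin * j1v[wo]] += ai[ho] * aj[wo] * g;
      }
    }
  }
  return dx;
}

// Rotate a single-channel image (matrix H x W) about its center.
// method 0 = nearest neighbor, 1 = bilinear; out-of-frame pixels are 0.
// [[Rcpp::export(name = ".rotate2d")]]
NumericMatrix rotate2d_cpp(NumericMatrix x, double angle_deg, int method) {
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix y(H, W);
  const double th = angle_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      // inverse mapping: rotate the output grid back into the source
      const double dy = i - cy, dx = j - cx;
      const double si = ct * dy + st * dx + cy;
      const double sj = -st * dy + ct * dx + cx;
      if (method == 0) {
        const int ri = (int)std::lround(si), rj = (int)std::lround(sj);
        if (ri >= 0 && ri < H && rj >= 0 && rj < W) y(i, j) = x(ri, rj);
      } else {
        if (si < 0 || si > H - 1 || sj < 0 || sj > W - 1) continue;
        const int i0 = (int)std::floor(si), j0 = (int)std::floor(sj);
        const int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1);
        const double a = si - i0, b = sj - j0;
        y(i, j) = (1 - a) * ((1 - b) * x(i0, j0) + b * x(i0, j1)) +
                  a * ((1 - b) * x(i1, j0) + b * x(i1, j1));
      }
    }
  }
  return y;
}

// 4-connected component labeling of a binary matrix (BFS flood fill).
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components_cpp(IntegerMatrix m) {
  const int H = m.nrow(), W = m.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (m(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i + H * j);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % H, pj = p / H;
        const int ni[4] = {pi - 1, pi + 1, pi, pi};
        const int nj[4] = {pj, pj, pj - 1, pj + 1};
        for (int t = 0; t < 4; ++t) {
          if (ni[t] < 0 || ni[t] >= H || nj[t] < 0 || nj[t] >= W) continue;
          if (m(ni[t], nj[t]) != 0 && lab(ni[t], nj[t]) == 0) {
            lab(ni[t], nj[t]) = next;
            stack.push_back(ni[t] + H * nj[t]);
          }
        }
      }
    }
  }
  return lab;
}
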