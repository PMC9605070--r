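// Low-level numerical kernels for the 3D encoder-decoder and the elastic warp.
//
// Tensor layout follows R's column-major arrays:
//   feature maps: dim = (W, H, D, C, N)   -- voxel index fastest, batch slowest
//   3x3x3 conv weights: dim = (3, 3, 3, Cin, Cout); 1x1x1 weights: (Cin, Cout)
//   displacement fields: dim = (W, H, D, 3), components in voxel units
//
// Convolutions are evaluated as GEMMs on an im2col matrix laid out (V x 27*Cin)
// so that both the matrix fill and the output write-back are contiguous.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::uword spatial_len(const IntegerVector& d) {
  return (arma::uword)d[0] * (arma::uword)d[1] * (arma::uword)d[2];
}

// Fill Mt (V x 27*Cin) for one sample with zero padding 1. Column order is
// offset-fastest within channel: col = o + 27*c with o = (di+1) + 3*(dj+1) + 9*(dk+1).
static void im2col3(const double* x, int W, int H, int D, int Cin, arma::mat& Mt) {
  const arma::uword V = (arma::uword)W * H * D;
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + (arma::uword)c * V;
    for (int dk = -1; dk <= 1; ++dk) {
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          const int o = (di + 1) + 3 * (dj + 1) + 9 * (dk + 1);
          double* col = Mt.colptr(o + 27 * c);
          arma::uword v = 0;
          for (int k = 0; k < D; ++k) {
            const int sk = k + dk;
            for (int j = 0; j < H; ++j) {
              const int sj = j + dj;
              const bool ok_jk = (sk >= 0 && sk < D && sj >= 0 && sj < H);
              const double* src = xc + (arma::uword)W * (sj + (arma::uword)H * sk);
              for (int i = 0; i < W; ++i, ++v) {
                const int si = i + di;
                col[v] = (ok_jk && si >= 0 && si < W) ? src[si] : 0.0;
              }
            }
          }
        }
      }
    }
  }
}

// Scatter-add the col2im adjoint of im2col3: dx(src) += Gt(v, o + 27*c).
static void col2im3(const arma::mat& Gt, int W, int H, int D, int Cin, double* dx) {
  const arma::uword V = (arma::uword)W * H * D;
  for (int c = 0; c < Cin; ++c) {
    double* xc = dx + (arma::uword)c * V;
    for (int dk = -1; dk <= 1; ++dk) {
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          const int o = (di + 1) + 3 * (dj + 1) + 9 * (dk + 1);
          const double* col = Gt.colptr(o + 27 * c);
          arma::uword v = 0;
          for (int k = 0; k < D; ++k) {
            const int sk = k + dk;
            for (int j = 0; j < H; ++j) {
              const int sj = j + dj;
              const bool ok_jk = (sk >= 0 && sk < D && sj >= 0 && sj < H);
              double* dst = xc + (arma::uword)W * (sj + (arma::uword)H * sk);
              for (int i = 0; i < W; ++i, ++v) {
                const int si = i + di;
                if (ok_jk && si >= 0 && si < W) dst[si] += col[v];
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3_fwd(NumericVector x, IntegerVector xdim,
                            NumericVector w, NumericVector b) {
  const int W = xdim[0], H = xdim[1], D = xdim[2], Cin = xdim[3], N = xdim[4];
  const int Cout = b.size();
  const arma::uword V = spatial_len(xdim);
  NumericVector y((arma::uword)V * Cout * N);
  arma::mat Wm(w.begin(), 27 * Cin, Cout, false, true);
  arma::mat Mt(V, 27 * (arma::uword)Cin);
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin() + (arma::uword)n * V * Cin, W, H, D, Cin, Mt);
    arma::mat Yt(y.begin() + (arma::uword)n * V * Cout, V, Cout, false, true);
    Yt = Mt * Wm;
    for (int co = 0; co < Cout; ++co) Yt.col(co) += b[co];
  }
  y.attr("dim") = IntegerVector::create(W, H, D, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv3_bwd(NumericVector x, IntegerVector xdim,
                   NumericVector w, NumericVector dy, int Cout) {
  const int W = xdim[0], H = xdim[1], D = xdim[2], Cin = xdim[3], N = xdim[4];
  const arma::uword V = spatial_len(xdim);
  NumericVector dx((arma::uword)V * Cin * N);
  NumericVector dw(w.size());
  NumericVector db(Cout);
  arma::mat Wm(w.begin(), 27 * Cin, Cout, false, true);
  arma::mat dWm(dw.begin(), 27 * Cin, Cout, false, true);
  arma::vec dB(db.begin(), Cout, false, true);
  arma::mat Mt(V, 27 * (arma::uword)Cin);
  for (int n = 0; n < N; ++n) {
    arma::mat Dyt(dy.begin() + (arma::uword)n * V * Cout, V, Cout, false, true);
    im2col3(x.begin() + (arma::uword)n * V * Cin, W, H, D, Cin, Mt);
    dWm += Mt.t() * Dyt;
    dB += arma::sum(Dyt, 0).t();
    arma::mat Gt = Dyt * Wm.t();  // V x 27*Cin
    col2im3(Gt, W, H, D, Cin, dx.begin() + (arma::uword)n * V * Cin);
  }
  dx.attr("dim") = xdim;
  dw.attr("dim") = IntegerVector::create(3, 3, 3, Cin, Cout);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
NumericVector cpp_conv1_fwd(NumericVector x, IntegerVector xdim,
                            NumericVector w, NumericVector b) {
  const int W = xdim[0], H = xdim[1], D = xdim[2], Cin = xdim[3], N = xdim[4];
  const int Cout = b.size();
  const arma::uword V = spatial_len(xdim);
  NumericVector y((arma::uword)V * Cout * N);
  arma::mat Wm(w.begin(), Cin, Cout, false, true);
  for (int n = 0; n < N; ++n) {
    arma::mat Xt(x.begin() + (arma::uword)n * V * Cin, V, Cin, false, true);
    arma::mat Yt(y.begin() + (arma::uword)n * V * Cout, V, Cout, false, true);
    Yt = Xt * Wm;
    for (int co = 0; co < Cout; ++co) Yt.col(co) += b[co];
  }
  y.attr("dim") = IntegerVector::create(W, H, D, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv1_bwd(NumericVector x, IntegerVector xdim,
                   NumericVector w, NumericVector dy, int Cout) {
  const int Cin = xdim[3], N = xdim[4];
  const arma::uword V = spatial_len(xdim);
  NumericVector dx(x.size());
  NumericVector dw(w.size());
  NumericVector db(Cout);
  arma::mat Wm(w.begin(), Cin, Cout, false, true);
  arma::mat dWm(dw.begin(), Cin, Cout, false, true);
  arma::vec dB(db.begin(), Cout, false, true);
  for (int n = 0; n < N; ++n) {
    arma::mat Xt(x.begin() + (arma::uword)n * V * Cin, V, Cin, false, true);
    arma::mat Dyt(dy.begin() + (arma::uword)n * V * Cout, V, Cout, false, true);
    arma::mat Dxt(dx.begin() + (arma::uword)n * V * Cin, V, Cin, false, true);
    Dxt = Dyt * Wm.t();
    dWm += Xt.t() * Dyt;
    dB += arma::sum(Dyt, 0).t();
  }
  dx.attr("dim") = xdim;
  dw.attr("dim") = IntegerVector::create(Cin, Cout);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2x2 max pooling, stride 2. Returns pooled tensor and flat argmax indices
// (0-based into the input vector) for the backward scatter.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x, IntegerVector xdim) {
  const int W = xdim[0], H = xdim[1], D = xdim[2], C = xdim[3], N = xdim[4];
  const int Wo = W / 2, Ho = H / 2, Do = D / 2;
  const arma::uword Vo = (arma::uword)Wo * Ho * Do;
  NumericVector y(Vo * C * N);
  IntegerVector idx(Vo * C * N);
  const arma::uword V = spatial_len(xdim);
  arma::uword u = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const arma::uword base = ((arma::uword)n * C + c) * V;
      for (int k = 0; k < Do; ++k) {
        for (int j = 0; j < Ho; ++j) {
          for (int i = 0; i < Wo; ++i, ++u) {
            double best = -INFINITY; arma::uword bidx = 0;
            for (int dk = 0; dk < 2; ++dk)
              for (int dj = 0; dj < 2; ++dj)
                for (int di = 0; di < 2; ++di) {
                  const arma::uword s = base + (arma::uword)(2 * i + di)
                    + (arma::uword)W * ((2 * j + dj) + (arma::uword)H * (2 * k + dk));
                  if (x[s] > best) { best = x[s]; bidx = s; }
                }
            y[u] = best; idx[u] = (int)bidx;
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Wo, Ho, Do, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, IntegerVector idx,
                               IntegerVector xdim) {
  NumericVector dx((arma::uword)spatial_len(xdim) * xdim[3] * xdim[4]);
  for (R_xlen_t u = 0; u < dy.size(); ++u) dx[idx[u]] += dy[u];
  dx.attr("dim") = xdim;
  return dx;
}

// Trilinear x2 upsampling with half-voxel-centre alignment and edge clamping:
// output voxel i samples the input at i/2 - 0.25.
static inline void up2_weights(int i, int n_in, int& i0, int& i1, double& t) {
  double s = 0.5 * i - 0.25;
  int f = (int)std::floor(s);
  t = s - f;
  i0 = std::min(std::max(f, 0), n_in - 1);
  i1 = std::min(std::max(f + 1, 0), n_in - 1);
}

// [[Rcpp::export]]
NumericVector cpp_uptri2_fwd(NumericVector x, IntegerVector xdim) {
  const int W = xdim[0], H = xdim[1], D = xdim[2], C = xdim[3], N = xdim[4];
  const int Wo = 2 * W, Ho = 2 * H, Do = 2 * D;
  const arma::uword V = spatial_len(xdim), Vo = (arma::uword)Wo * Ho * Do;
  NumericVector y(Vo * C * N);
  std::vector<int> i0(Wo), i1(Wo), j0(Ho), j1(Ho), k0(Do), k1(Do);
  std::vector<double> ti(Wo), tj(Ho), tk(Do);
  for (int i = 0; i < Wo; ++i) up2_weights(i, W, i0[i], i1[i], ti[i]);
  for (int j = 0; j < Ho; ++j) up2_weights(j, H, j0[j], j1[j], tj[j]);
  for (int k = 0; k < Do; ++k) up2_weights(k, D, k0[k], k1[k], tk[k]);
  arma::uword u = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((arma::uword)n * C + c) * V;
      for (int k = 0; k < Do; ++k)
        for (int j = 0; j < Ho; ++j)
          for (int i = 0; i < Wo; ++i, ++u) {
            const double wi1 = ti[i], wj1 = tj[j], wk1 = tk[k];
            const double wi0 = 1 - wi1, wj0 = 1 - wj1, wk0 = 1 - wk1;
            auto at = [&](int a, int b, int cc) {
              return xc[(arma::uword)a + (arma::uword)W * (b + (arma::uword)H * cc)];
            };
            y[u] =
              wk0 * (wj0 * (wi0 * at(i0[i], j0[j], k0[k]) + wi1 * at(i1[i], j0[j], k0[k]))
                   + wj1 * (wi0 * at(i0[i], j1[j], k0[k]) + wi1 * at(i1[i], j1[j], k0[k])))
            + wk1 * (wj0 * (wi0 * at(i0[i], j0[j], k1[k]) + wi1 * at(i1[i], j0[j], k1[k]))
                   + wj1 * (wi0 * at(i0[i], j1[j], k1[k]) + wi1 * at(i1[i], j1[j], k1[k])));
          }
    }
  y.attr("dim") = IntegerVector::create(Wo, Ho, Do, C, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_uptri2_bwd(NumericVector dy, IntegerVector ydim) {
  const int Wo = ydim[0], Ho = ydim[1], Do = ydim[2], C = ydim[3], N = ydim[4];
  const int W = Wo / 2, H = Ho / 2, D = Do / 2;
  const arma::uword V = (arma::uword)W * H * D, Vo = spatial_len(ydim);
  NumericVector dx(V * C * N);
  std::vector<int> i0(Wo), i1(Wo), j0(Ho), j1(Ho), k0(Do), k1(Do);
  std::vector<double> ti(Wo), tj(Ho), tk(Do);
  for (int i = 0; i < Wo; ++i) up2_weights(i, W, i0[i], i1[i], ti[i]);
  for (int j = 0; j < Ho; ++j) up2_weights(j, H, j0[j], j1[j], tj[j]);
  for (int k = 0; k < Do; ++k) up2_weights(k, D, k0[k], k1[k], tk[k]);
  arma::uword u = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xc = dx.begin() + ((arma::uword)n * C + c) * V;
      for (int k = 0; k < Do; ++k)
        for (int j = 0; j < Ho; ++j)
          for (int i = 0; i < Wo; ++i, ++u) {
            const double g = dy[u];
            if (g == 0) continue;
            const double wi1 = ti[i], wj1 = tj[j], wk1 = tk[k];
            const double wi0 = 1 - wi1, wj0 = 1 - wj1, wk0 = 1 - wk1;
            auto add = [&](int a, int b, int cc, double wgt) {
              xc[(arma::uword)a + (arma::uword)W * (b + (arma::uword)H * cc)] += wgt * g;
            };
            add(i0[i], j0[j], k0[k], wk0 * wj0 * wi0);
            add(i1[i], j0[j], k0[k], wk0 * wj0 * wi1);
            add(i0[i], j1[j], k0[k], wk0 * wj1 * wi0);
            add(i1[i], j1[j], k0[k], wk0 * wj1 * wi1);
            add(i0[i], j0[j], k1[k], wk1 * wj0 * wi0);
            add(i1[i], j0[j], k1[k], wk1 * wj0 * wi1);
            add(i0[i], j1[j], k1[k], wk1 * wj1 * wi0);
            add(i1[i], j1[j], k1[k], wk1 * wj1 * wi1);
          }
    }
  dx.attr("dim") = IntegerVector::create(W, H, D, C, N);
  return dx;
}

// Nearest-neighbour integer-factor upsampling (for the deep supervision taps).
// [[Rcpp::export]]
NumericVector cpp_upnn_fwd(NumericVector x, IntegerVector xdim, int f) {
  const int W = xdim[0], H = xdim[1], D = xdim[2], C = xdim[3], N = xdim[4];
  const int Wo = W * f, Ho = H * f, Do = D * f;
  const arma::uword V = spatial_len(xdim), Vo = (arma::uword)Wo * Ho * Do;
  NumericVector y(Vo * C * N);
  arma::uword u = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((arma::uword)n * C + c) * V;
      for (int k = 0; k < Do; ++k)
        for (int j = 0; j < Ho; ++j)
          for (int i = 0; i < Wo; ++i, ++u)
            y[u] = xc[(arma::uword)(i / f) + (arma::uword)W * ((j / f) + (arma::uword)H * (k / f))];
    }
  y.attr("dim") = IntegerVector::create(Wo, Ho, Do, C, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upnn_bwd(NumericVector dy, IntegerVector ydim, int f) {
  const int Wo = ydim[0], Ho = ydim[1], Do = ydim[2], C = ydim[3], N = ydim[4];
  const int W = Wo / f, H = Ho / f, D = Do / f;
  const arma::uword V = (arma::uword)W * H * D;
  NumericVector dx(V * C * N);
  arma::uword u = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xc = dx.begin() + ((arma::uword)n * C + c) * V;
      for (int k = 0; k < Do; ++k)
        for (int j = 0; j < Ho; ++j)
          for (int i = 0; i < Wo; ++i, ++u)
            xc[(arma::uword)(i / f) + (arma::uword)W * ((j / f) + (arma::uword)H * (k / f))] += dy[u];
    }
  dx.attr("dim") = IntegerVector::create(W, H, D, C, N);
  return dx;
}

// Batch normalisation over (W,H,D,N) per channel.
// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, IntegerVector xdim, NumericVector gamma,
                NumericVector beta, bool training, NumericVector rmean,
                NumericVector rvar, double eps) {
  const int C = xdim[3], N = xdim[4];
  const arma::uword V = spatial_len(xdim);
  NumericVector y(x.size());
  NumericVector mean(C), invstd(C), bvar(C);
  const double M = (double)V * N;
  for (int c = 0; c < C; ++c) {
    double mu, var;
    if (training) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* xc = x.begin() + ((arma::uword)n * C + c) * V;
        for (arma::uword v = 0; v < V; ++v) { s += xc[v]; s2 += xc[v] * xc[v]; }
      }
      mu = s / M;
      var = s2 / M - mu * mu;
      if (var < 0) var = 0;
    } else {
      mu = rmean[c]; var = rvar[c];
    }
    const double is = 1.0 / std::sqrt(var + eps);
    mean[c] = mu; invstd[c] = is; bvar[c] = var;
    const double g = gamma[c], b = beta[c];
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((arma::uword)n * C + c) * V;
      double* yc = y.begin() + ((arma::uword)n * C + c) * V;
      for (arma::uword v = 0; v < V; ++v) yc[v] = g * (xc[v] - mu) * is + b;
    }
  }
  y.attr("dim") = xdim;
  return List::create(_["y"] = y, _["mean"] = mean, _["invstd"] = invstd, _["var"] = bvar);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, IntegerVector xdim, NumericVector dy,
                NumericVector gamma, NumericVector mean, NumericVector invstd) {
  const int C = xdim[3], N = xdim[4];
  const arma::uword V = spatial_len(xdim);
  NumericVector dx(x.size()), dgamma(C), dbeta(C);
  const double M = (double)V * N;
  for (int c = 0; c < C; ++c) {
    const double mu = mean[c], is = invstd[c], g = gamma[c];
    double sum_dy = 0, sum_dy_xhat = 0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((arma::uword)n * C + c) * V;
      const double* dyc = dy.begin() + ((arma::uword)n * C + c) * V;
      for (arma::uword v = 0; v < V; ++v) {
        const double xh = (xc[v] - mu) * is;
        sum_dy += dyc[v];
        sum_dy_xhat += dyc[v] * xh;
      }
    }
    dbeta[c] = sum_dy;
    dgamma[c] = sum_dy_xhat;
    const double k1 = g * is / M;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((arma::uword)n * C + c) * V;
      const double* dyc = dy.begin() + ((arma::uword)n * C + c) * V;
      double* dxc = dx.begin() + ((arma::uword)n * C + c) * V;
      for (arma::uword v = 0; v < V; ++v) {
        const double xh = (xc[v] - mu) * is;
        dxc[v] = k1 * (M * dyc[v] - sum_dy - xh * sum_dy_xhat);
      }
    }
  }
  dx.attr("dim") = xdim;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Backward warp of a single 3D image: out(v) = img(v + field(v)).
// Sample positions outside the volume read 0 (air background).
// [[Rcpp::export]]
NumericVector cpp_warp_fwd(NumericVector img, IntegerVector dim3,
                           NumericVector field, bool nearest) {
  const int W = dim3[0], H = dim3[1], D = dim3[2];
  const arma::uword V = (arma::uword)W * H * D;
  NumericVector out(V);
  const double* fx = field.begin();
  const double* fy = field.begin() + V;
  const double* fz = field.begin() + 2 * V;
  arma::uword v = 0;
  for (int k = 0; k < D; ++k)
    for (int j = 0; j < H; ++j)
      for (int i = 0; i < W; ++i, ++v) {
        const double sx = i + fx[v], sy = j + fy[v], sz = k + fz[v];
        if (nearest) {
          const long ri = std::lround(sx), rj = std::lround(sy), rk = std::lround(sz);
          out[v] = (ri >= 0 && ri < W && rj >= 0 && rj < H && rk >= 0 && rk < D)
            ? img[(arma::uword)ri + (arma::uword)W * (rj + (arma::uword)H * rk)] : 0.0;
        } else {
          const int i0 = (int)std::floor(sx), j0 = (int)std::floor(sy), k0 = (int)std::floor(sz);
          const double ti = sx - i0, tj = sy - j0, tk = sz - k0;
          double acc = 0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                const int a = i0 + di, b = j0 + dj, c = k0 + dk;
                if (a < 0 || a >= W || b < 0 || b >= H || c < 0 || c >= D) continue;
                const double wgt = (di ? ti : 1 - ti) * (dj ? tj : 1 - tj) * (dk ? tk : 1 - tk);
                acc += wgt * img[(arma::uword)a + (arma::uword)W * (b + (arma::uword)H * c)];
              }
          out[v] = acc;
        }
      }
  out.attr("dim") = dim3;
  return out;
}

// Adjoint of the trilinear warp with respect to the image (the warp is linear
// in the image for a fixed field), needed for consistency-loss gradients.
// [[Rcpp::export]]
NumericVector cpp_warp_bwd(NumericVector dout, IntegerVector dim3,
                           NumericVector field) {
  const int W = dim3[0], H = dim3[1], D = dim3[2];
  const arma::uword V = (arma::uword)W * H * D;
  NumericVector dimg(V);
  const double* fx = field.begin();
  const double* fy = field.begin() + V;
  const double* fz = field.begin() + 2 * V;
  arma::uword v = 0;
  for (int k = 0; k < D; ++k)
    for (int j = 0; j < H; ++j)
      for (int i = 0; i < W; ++i, ++v) {
        const double g = dout[v];
        if (g == 0) continue;
        const double sx = i + fx[v], sy = j + fy[v], sz = k + fz[v];
        const int i0 = (int)std::floor(sx), j0 = (int)std::floor(sy), k0 = (int)std::floor(sz);
        const double ti = sx - i0, tj = sy - j0, tk = sz - k0;
        for (int dk = 0; dk < 2; ++dk)
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              const int a = i0 + di, b = j0 + dj, c = k0 + dk;
              if (a < 0 || a >= W || b < 0 || b >= H || c < 0 || c >= D) continue;
              const double wgt = (di ? ti : 1 - ti) * (dj ? tj : 1 - tj) * (dk ? tk : 1 - tk);
              dimg[(arma::uword)a + (arma::uword)W * (b + (arma::uword)H * c)] += wgt * g;
            }
      }
  dimg.attr("dim") = dim3;
  return dimg;
}

// 26-connected component labelling of a binary 3D mask (BFS).
// [[Rcpp::export]]
IntegerVector cpp_conncomp26(LogicalVector mask, IntegerVector dim3) {
  const int W = dim3[0], H = dim3[1], D = dim3[2];
  const arma::uword V = (arma::uword)W * H * D;
  IntegerVector lab(V);
  int next = 0;
  std::vector<arma::uword> queue;
  for (arma::uword s = 0; s < V; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    queue.clear();
    queue.push_back(s);
    while (!queue.empty()) {
      const arma::uword v = queue.back(); queue.pop_back();
      const int i = v % W, j = (v / W) % H, k = v / ((arma::uword)W * H);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            const int a = i + di, b = j + dj, c = k + dk;
            if (a < 0 || a >= W || b < 0 || b >= H || c < 0 || c >= D) continue;
            const arma::uword u = (arma::uword)a + (arma::uword)W * (b + (arma::uword)H * c);
            if (mask[u] && lab[u] == 0) { lab[u] = next; queue.push_back(u); }
          }
    }
  }
  lab.attr("dim") = dim3;
  return lab;
}

// Paint anti-aliased spheres (max-combined soft occupancy) along vessel
// centrelines; centres are 1-based voxel coordinates.
// [[Rcpp::export]]
NumericVector cpp_paint_spheres(NumericMatrix centres, NumericVector radii,
                                IntegerVector dim3) {
  const int W = dim3[0], H = dim3[1], D = dim3[2];
  NumericVector soft((arma::uword)W * H * D);
  for (int p = 0; p < centres.nrow(); ++p) {
    const double cx = centres(p, 0), cy = centres(p, 1), cz = centres(p, 2);
    const double r = radii[p];
    const int lo0 = std::max((int)std::floor(cx - r - 1), 1);
    const int hi0 = std::min((int)std::ceil(cx + r + 1), W);
    const int lo1 = std::max((int)std::floor(cy - r - 1), 1);
    const int hi1 = std::min((int)std::ceil(cy + r + 1), H);
    const int lo2 = std::max((int)std::floor(cz - r - 1), 1);
    const int hi2 = std::min((int)std::ceil(cz + r + 1), D);
    for (int k = lo2; k <= hi2; ++k)
      for (int j = lo1; j <= hi1; ++j)
        for (int i = lo0; i <= hi0; ++i) {
          const double dist = std::sqrt((i - cx) * (i - cx) +
                                        (j - cy) * (j - cy) +
                                        (k - cz) * (k - cz));
          double val = r + 0.5 - dist;
          if (val <= 0) continue;
          if (val > 1) val = 1;
          const arma::uword u = (arma::uword)(i - 1)
            + (arma::uword)W * ((j - 1) + (arma::uword)H * (k - 1));
          if (val > soft[u]) soft[u] = val;
        }
  }
  soft.attr("dim") = dim3;
  return soft;
}
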