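#include <Rcpp.h>
using namespace Rcpp;

// Tensor layout throughout: column-major R arrays with dim (D, H, W, C, N),
// i.e. depth index fastest. Weights: dim (k, k, k, Cin/groups, Cout).
// All convolutions are cubic-kernel, zero-padded, biasless.

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
NumericVector conv3d_fwd(NumericVector x, IntegerVector xdim,
                         NumericVector w, int k, int cout,
                         int groups, int stride, int pad) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3], N = xdim[4];
  const int cin_g = C / groups, cout_g = cout / groups;
  const int Do = out_size(D, k, stride, pad);
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  NumericVector y(R_xlen_t(Do) * Ho * Wo * cout * N);
  const double *px = x.begin(), *pw = w.begin();
  double *py = y.begin();
  const R_xlen_t xC = R_xlen_t(D) * H * W;      // stride per input channel
  const R_xlen_t xN = xC * C;
  const R_xlen_t yC = R_xlen_t(Do) * Ho * Wo;
  const R_xlen_t yN = yC * cout;
  const R_xlen_t wc = R_xlen_t(k) * k * k;      // per (ci) block
  const R_xlen_t wo = wc * cin_g;               // per (co) block

  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < cout; ++co) {
      const int g = co / cout_g;
      const double *wbase = pw + wo * co;
      for (int xo = 0; xo < Wo; ++xo) {
        const int x0 = xo * stride - pad;
        for (int yo = 0; yo < Ho; ++yo) {
          const int y0 = yo * stride - pad;
          for (int zo = 0; zo < Do; ++zo) {
            const int z0 = zo * stride - pad;
            double acc = 0.0;
            for (int ci = 0; ci < cin_g; ++ci) {
              const double *xc = px + xN * n + xC * (g * cin_g + ci);
              const double *wk = wbase + wc * ci;
              for (int kx = 0; kx < k; ++kx) {
                const int xi = x0 + kx;
                if (xi < 0 || xi >= W) continue;
                for (int ky = 0; ky < k; ++ky) {
                  const int yi = y0 + ky;
                  if (yi < 0 || yi >= H) continue;
                  const double *xcol = xc + R_xlen_t(D) * (yi + R_xlen_t(H) * xi);
                  const double *wcol = wk + k * (ky + k * kx);
                  for (int kz = 0; kz < k; ++kz) {
                    const int zi = z0 + kz;
                    if (zi < 0 || zi >= D) continue;
                    acc += xcol[zi] * wcol[kz];
                  }
                }
              }
            }
            py[yN * n + yC * co + R_xlen_t(Do) * (yo + R_xlen_t(Ho) * xo) + zo] = acc;
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, cout, N);
  return y;
}

// [[Rcpp::export]]
NumericVector conv3d_bwd_input(NumericVector gy, IntegerVector xdim,
                               NumericVector w, int k, int cout,
                               int groups, int stride, int pad) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3], N = xdim[4];
  const int cin_g = C / groups, cout_g = cout / groups;
  const int Do = out_size(D, k, stride, pad);
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  NumericVector gx(R_xlen_t(D) * H * W * C * N);
  const double *pg = gy.begin(), *pw = w.begin();
  double *px = gx.begin();
  const R_xlen_t xC = R_xlen_t(D) * H * W, xN = xC * C;
  const R_xlen_t yC = R_xlen_t(Do) * Ho * Wo, yN = yC * cout;
  const R_xlen_t wc = R_xlen_t(k) * k * k, wo = wc * cin_g;

  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < cout; ++co) {
      const int g = co / cout_g;
      const double *wbase = pw + wo * co;
      const double *gc = pg + yN * n + yC * co;
      for (int xo = 0; xo < Wo; ++xo) {
        const int x0 = xo * stride - pad;
        for (int yo = 0; yo < Ho; ++yo) {
          const int y0 = yo * stride - pad;
          for (int zo = 0; zo < Do; ++zo) {
            const int z0 = zo * stride - pad;
            const double gv = gc[R_xlen_t(Do) * (yo + R_xlen_t(Ho) * xo) + zo];
            if (gv == 0.0) continue;
            for (int ci = 0; ci < cin_g; ++ci) {
              double *xc = px + xN * n + xC * (g * cin_g + ci);
              const double *wk = wbase + wc * ci;
              for (int kx = 0; kx < k; ++kx) {
                const int xi = x0 + kx;
                if (xi < 0 || xi >= W) continue;
                for (int ky = 0; ky < k; ++ky) {
                  const int yi = y0 + ky;
                  if (yi < 0 || yi >= H) continue;
                  double *xcol = xc + R_xlen_t(D) * (yi + R_xlen_t(H) * xi);
                  const double *wcol = wk + k * (ky + k * kx);
                  for (int kz = 0; kz < k; ++kz) {
                    const int zi = z0 + kz;
                    if (zi < 0 || zi >= D) continue;
                    xcol[zi] += gv * wcol[kz];
                  }
                }
              }
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = xdim;
  return gx;
}

// [[Rcpp::export]]
NumericVector conv3d_bwd_weight(NumericVector x, IntegerVector xdim,
                                NumericVector gy, int k, int cout,
                                int groups, int stride, int pad) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3], N = xdim[4];
  const int cin_g = C / groups, cout_g = cout / groups;
  const int Do = out_size(D, k, stride, pad);
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  NumericVector gw(R_xlen_t(k) * k * k * cin_g * cout);
  const double *px = x.begin(), *pg = gy.begin();
  double *pw = gw.begin();
  const R_xlen_t xC = R_xlen_t(D) * H * W, xN = xC * C;
  const R_xlen_t yC = R_xlen_t(Do) * Ho * Wo, yN = yC * cout;
  const R_xlen_t wc = R_xlen_t(k) * k * k, wo = wc * cin_g;

  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < cout; ++co) {
      const int g = co / cout_g;
      const double *gc = pg + yN * n + yC * co;
      double *wbase = pw + wo * co;
      for (int xo = 0; xo < Wo; ++xo) {
        const int x0 = xo * stride - pad;
        for (int yo = 0; yo < Ho; ++yo) {
          const int y0 = yo * stride - pad;
          for (int zo = 0; zo < Do; ++zo) {
            const int z0 = zo * stride - pad;
            const double gv = gc[R_xlen_t(Do) * (yo + R_xlen_t(Ho) * xo) + zo];
            if (gv == 0.0) continue;
            for (int ci = 0; ci < cin_g; ++ci) {
              const double *xc = px + xN * n + xC * (g * cin_g + ci);
              double *wk = wbase + wc * ci;
              for (int kx = 0; kx < k; ++kx) {
                const int xi = x0 + kx;
                if (xi < 0 || xi >= W) continue;
                for (int ky = 0; ky < k; ++ky) {
                  const int yi = y0 + ky;
                  if (yi < 0 || yi >= H) continue;
                  const double *xcol = xc + R_xlen_t(D) * (yi + R_xlen_t(H) * xi);
                  double *wcol = wk + k * (ky + k * kx);
                  for (int kz = 0; kz < k; ++kz) {
                    const int zi = z0 + kz;
                    if (zi < 0 || zi >= D) continue;
                    wcol[kz] += gv * xcol[zi];
                  }
                }
              }
            }
          }
        }
      }
    }
  }
  gw.attr("dim") = IntegerVector::create(k, k, k, cin_g, cout);
  return gw;
}

// Max pooling. Returns the pooled tensor plus 1-based argmax indices into the
// flattened input, for the backward pass.
// [[Rcpp::export]]
List maxpool3d_fwd(NumericVector x, IntegerVector xdim,
                   int k, int stride, int pad) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3], N = xdim[4];
  const int Do = out_size(D, k, stride, pad);
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  const R_xlen_t ylen = R_xlen_t(Do) * Ho * Wo * C * N;
  NumericVector y(ylen);
  NumericVector amax(ylen);  // double to hold large indices safely
  const double *px = x.begin();
  double *py = y.begin(), *pa = amax.begin();
  const R_xlen_t xC = R_xlen_t(D) * H * W;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *xc = px + xC * (c + R_xlen_t(C) * n);
      const R_xlen_t base = xC * (c + R_xlen_t(C) * n);
      for (int xo = 0; xo < Wo; ++xo) {
        for (int yo = 0; yo < Ho; ++yo) {
          for (int zo = 0; zo < Do; ++zo) {
            double best = R_NegInf;
            R_xlen_t besti = -1;
            for (int kx = 0; kx < k; ++kx) {
              const int xi = xo * stride - pad + kx;
              if (xi < 0 || xi >= W) continue;
              for (int ky = 0; ky < k; ++ky) {
                const int yi = yo * stride - pad + ky;
                if (yi < 0 || yi >= H) continue;
                for (int kz = 0; kz < k; ++kz) {
                  const int zi = zo * stride - pad + kz;
                  if (zi < 0 || zi >= D) continue;
                  const R_xlen_t idx = zi + R_xlen_t(D) * (yi + R_xlen_t(H) * xi);
                  const double v = xc[idx];
                  if (v > best) { best = v; besti = base + idx; }
                }
              }
            }
            const R_xlen_t oidx =
              zo + R_xlen_t(Do) * (yo + R_xlen_t(Ho) * (xo + R_xlen_t(Wo) * (c + R_xlen_t(C) * n)));
            py[oidx] = best;
            pa[oidx] = double(besti + 1);
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, C, N);
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bwd(NumericVector gy, NumericVector argmax,
                            IntegerVector xdim) {
  NumericVector gx(R_xlen_t(xdim[0]) * xdim[1] * xdim[2] * xdim[3] * xdim[4]);
  const double *pg = gy.begin(), *pa = argmax.begin();
  double *px = gx.begin();
  const R_xlen_t m = gy.size();
  for (R_xlen_t i = 0; i < m; ++i) px[R_xlen_t(pa[i]) - 1] += pg[i];
  gx.attr("dim") = xdim;
  return gx;
}

// im2col for cubic kernels: returns an (OutVox * N) x (k^3 * C) matrix whose
// row r = vox + OutVox * n holds the receptive field of output voxel vox of
// sample n (vox in (Do,Ho,Wo) column-major order). Column c = kz + k*(ky +
// k*(kx + k*ci)) matches the weight layout flattened per output channel.
// [[Rcpp::export]]
NumericMatrix im2col3d(NumericVector x, IntegerVector xdim,
                       int k, int stride, int pad) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3], N = xdim[4];
  const int Do = out_size(D, k, stride, pad);
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  const R_xlen_t ov = R_xlen_t(Do) * Ho * Wo;
  NumericMatrix M(ov * N, R_xlen_t(k) * k * k * C);
  const double *px = x.begin();
  double *pm = M.begin();
  const R_xlen_t xC = R_xlen_t(D) * H * W, xN = xC * C;
  const R_xlen_t nrow = ov * N;
  for (int ci = 0; ci < C; ++ci) {
    for (int kx = 0; kx < k; ++kx) for (int ky = 0; ky < k; ++ky)
      for (int kz = 0; kz < k; ++kz) {
        const R_xlen_t col = kz + R_xlen_t(k) * (ky + R_xlen_t(k) * (kx + R_xlen_t(k) * ci));
        double *mcol = pm + nrow * col;
        for (int n = 0; n < N; ++n) {
          const double *xc = px + xN * n + xC * ci;
          double *mrow = mcol + ov * n;
          for (int xo = 0; xo < Wo; ++xo) {
            const int xi = xo * stride - pad + kx;
            const bool xok = xi >= 0 && xi < W;
            for (int yo = 0; yo < Ho; ++yo) {
              const int yi = yo * stride - pad + ky;
              const bool yok = yi >= 0 && yi < H;
              const double *xcol = xok && yok ?
                xc + R_xlen_t(D) * (yi + R_xlen_t(H) * xi) : nullptr;
              double *mr = mrow + R_xlen_t(Do) * (yo + R_xlen_t(Ho) * xo);
              for (int zo = 0; zo < Do; ++zo) {
                const int zi = zo * stride - pad + kz;
                mr[zo] = (xcol && zi >= 0 && zi < D) ? xcol[zi] : 0.0;
              }
            }
          }
        }
      }
  }
  return M;
}

// Scatter-add of an im2col-layout gradient back to input space.
// [[Rcpp::export]]
NumericVector col2im3d(NumericMatrix M, IntegerVector xdim,
                       int k, int stride, int pad) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3], N = xdim[4];
  const int Do = out_size(D, k, stride, pad);
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  const R_xlen_t ov = R_xlen_t(Do) * Ho * Wo;
  NumericVector gx(R_xlen_t(D) * H * W * C * N);
  const double *pm = M.begin();
  double *px = gx.begin();
  const R_xlen_t xC = R_xlen_t(D) * H * W, xN = xC * C;
  const R_xlen_t nrow = ov * N;
  for (int ci = 0; ci < C; ++ci) {
    for (int kx = 0; kx < k; ++kx) for (int ky = 0; ky < k; ++ky)
      for (int kz = 0; kz < k; ++kz) {
        const R_xlen_t col = kz + R_xlen_t(k) * (ky + R_xlen_t(k) * (kx + R_xlen_t(k) * ci));
        const double *mcol = pm + nrow * col;
        for (int n = 0; n < N; ++n) {
          double *xc = px + xN * n + xC * ci;
          const double *mrow = mcol + ov * n;
          for (int xo = 0; xo < Wo; ++xo) {
            const int xi = xo * stride - pad + kx;
            if (xi < 0 || xi >= W) continue;
            for (int yo = 0; yo < Ho; ++yo) {
              const int yi = yo * stride - pad + ky;
              if (yi < 0 || yi >= H) continue;
              double *xcol = xc + R_xlen_t(D) * (yi + R_xlen_t(H) * xi);
              const double *mr = mrow + R_xlen_t(Do) * (yo + R_xlen_t(Ho) * xo);
              for (int zo = 0; zo < Do; ++zo) {
                const int zi = zo * stride - pad + kz;
                if (zi >= 0 && zi < D) xcol[zi] += mr[zo];
              }
            }
          }
        }
      }
  }
  gx.attr("dim") = xdim;
  return gx;
}
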