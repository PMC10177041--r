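#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Tensor layout throughout: R arrays dim (H, W, C, N), column-major, so the
// linear index of (h, w, c, n) is h + H*(w + W*(c + C*n)).  im2col rows are
// ordered (h, w, n) with h fastest; columns are ordered (c, dw, dh) with c
// fastest, i.e. col = c + C*(dw + k*dh).  Zero padding ("same", k odd).

static void im2col(const double* x, int H, int W, int C, int N, int k,
                   arma::mat& M) {
  const int p = k / 2;
  for (int dh = 0; dh < k; ++dh) {
    for (int dw = 0; dw < k; ++dw) {
      for (int c = 0; c < C; ++c) {
        const int col = c + C * (dw + k * dh);
        double* Mc = M.colptr(col);
        const int sh0 = dh - p;
        const int h_lo = std::max(0, -sh0);
        const int h_hi = std::min(H, H - sh0);
        for (int n = 0; n < N; ++n) {
          const double* xc = x + (size_t)H * W * (c + (size_t)C * n);
          for (int w = 0; w < W; ++w) {
            double* Mrow = Mc + (size_t)H * (w + (size_t)W * n);
            const int sw = w + dw - p;
            if (sw < 0 || sw >= W) {
              std::fill(Mrow, Mrow + H, 0.0);
              continue;
            }
            const double* xcol = xc + (size_t)H * sw;
            for (int h = 0; h < h_lo; ++h) Mrow[h] = 0.0;
            for (int h = h_lo; h < h_hi; ++h) Mrow[h] = xcol[h + sh0];
            for (int h = h_hi; h < H; ++h) Mrow[h] = 0.0;
          }
        }
      }
    }
  }
}

// adjoint of im2col: scatter-add M back into dx
static void col2im(const arma::mat& M, int H, int W, int C, int N, int k,
                   double* dx) {
  const int p = k / 2;
  std::fill(dx, dx + (size_t)H * W * C * N, 0.0);
  for (int dh = 0; dh < k; ++dh) {
    for (int dw = 0; dw < k; ++dw) {
      for (int c = 0; c < C; ++c) {
        const int col = c + C * (dw + k * dh);
        const double* Mc = M.colptr(col);
        const int sh0 = dh - p;
        const int h_lo = std::max(0, -sh0);
        const int h_hi = std::min(H, H - sh0);
        for (int n = 0; n < N; ++n) {
          double* xc = dx + (size_t)H * W * (c + (size_t)C * n);
          for (int w = 0; w < W; ++w) {
            const int sw = w + dw - p;
            if (sw < 0 || sw >= W) continue;
            const double* Mrow = Mc + (size_t)H * (w + (size_t)W * n);
            double* xcol = xc + (size_t)H * sw;
            for (int h = h_lo; h < h_hi; ++h) xcol[h + sh0] += Mrow[h];
          }
        }
      }
    }
  }
}

// When keep_m is true the im2col matrix is returned alongside y so the
// backward pass can reuse it instead of rebuilding it.
// [[Rcpp::export]]
List cpp_conv_fwd(NumericVector x, NumericMatrix Wm, NumericVector b,
                  int k, bool relu, bool keep_m) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int F = Wm.ncol();
  // M lives in R-owned memory so returning it costs no copy
  NumericMatrix Mr((size_t)H * W * N, (size_t)k * k * C);
  arma::mat M(Mr.begin(), Mr.nrow(), Mr.ncol(), false);
  im2col(x.begin(), H, W, C, N, k, M);
  const arma::mat Wmat(Wm.begin(), Wm.nrow(), F, false);
  arma::mat Y = M * Wmat;
  Y.each_row() += arma::rowvec(b.begin(), F, false);
  if (relu) Y.transform([](double v) { return v > 0 ? v : 0.0; });
  NumericVector out((size_t)H * W * F * N);
  out.attr("dim") = IntegerVector::create(H, W, F, N);
  double* o = out.begin();
  for (int f = 0; f < F; ++f) {
    const double* Yc = Y.colptr(f);
    for (int n = 0; n < N; ++n) {
      std::copy(Yc + (size_t)H * W * n, Yc + (size_t)H * W * (n + 1),
                o + (size_t)H * W * (f + (size_t)F * n));
    }
  }
  if (keep_m) return List::create(_["y"] = out, _["M"] = Mr);
  return List::create(_["y"] = out);
}

// y is the forward output (post-ReLU when relu=true), used as the ReLU mask;
// Mr is the im2col matrix cached by cpp_conv_fwd. Input spatial/channel
// geometry is passed explicitly since x itself is no longer needed.
// [[Rcpp::export]]
List cpp_conv_bwd(NumericMatrix Mr, NumericVector y, NumericVector dy,
                  NumericMatrix Wm, int k, bool relu, int C) {
  IntegerVector d = y.attr("dim");
  const int H = d[0], W = d[1], F = d[2], N = d[3];
  const size_t npix = (size_t)H * W * N;
  // dY as matrix rows (h,w,n), cols f, with ReLU mask applied
  arma::mat dY(npix, F);
  const double* dyp = dy.begin();
  const double* yp = y.begin();
  for (int f = 0; f < F; ++f) {
    double* col = dY.colptr(f);
    for (int n = 0; n < N; ++n) {
      const size_t src = (size_t)H * W * (f + (size_t)F * n);
      const size_t dst = (size_t)H * W * n;
      if (relu) {
        for (size_t i = 0; i < (size_t)H * W; ++i)
          col[dst + i] = yp[src + i] > 0 ? dyp[src + i] : 0.0;
      } else {
        std::copy(dyp + src, dyp + src + (size_t)H * W, col + dst);
      }
    }
  }
  const arma::mat M(Mr.begin(), Mr.nrow(), Mr.ncol(), false);
  const arma::mat Wmat(Wm.begin(), Wm.nrow(), F, false);
  arma::mat dW = M.t() * dY;
  arma::rowvec db = arma::sum(dY, 0);
  arma::mat dM = dY * Wmat.t();
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  col2im(dM, H, W, C, N, k, dx.begin());
  return List::create(_["dx"] = dx,
                      _["dW"] = wrap(dW),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2 max pooling, stride 2; H and W must be even.
// [[Rcpp::export]]
List cpp_pool_fwd(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int H2 = H / 2, W2 = W / 2;
  NumericVector y((size_t)H2 * W2 * C * N);
  IntegerVector idx((size_t)H2 * W2 * C * N);
  y.attr("dim") = IntegerVector::create(H2, W2, C, N);
  idx.attr("dim") = IntegerVector::create(H2, W2, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* plane = xp + (size_t)H * W * (c + (size_t)C * n);
      for (int w = 0; w < W2; ++w) {
        for (int h = 0; h < H2; ++h, ++o) {
          const size_t base = (size_t)(2 * h) + (size_t)H * (2 * w);
          double best = plane[base];
          int bi = 0;
          const double v1 = plane[base + 1];
          if (v1 > best) { best = v1; bi = 1; }
          const double v2 = plane[base + H];
          if (v2 > best) { best = v2; bi = 2; }
          const double v3 = plane[base + H + 1];
          if (v3 > best) { best = v3; bi = 3; }
          yp[o] = best;
          ip[o] = bi;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_pool_bwd(NumericVector dy, IntegerVector idx, int H, int W) {
  IntegerVector d = dy.attr("dim");
  const int H2 = d[0], W2 = d[1], C = d[2], N = d[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  double* dxp = dx.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* plane = dxp + (size_t)H * W * (c + (size_t)C * n);
      for (int w = 0; w < W2; ++w) {
        for (int h = 0; h < H2; ++h, ++o) {
          const size_t base = (size_t)(2 * h) + (size_t)H * (2 * w);
          const int bi = ip[o];
          plane[base + (bi / 2) * H + (bi % 2)] += dyp[o];
        }
      }
    }
  }
  return dx;
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Bilinear resize of an (H,W,C) image to (H2,W2); half-pixel-center mapping:
// src = (dst + 0.5) * (n_src / n_dst) - 0.5, edge-clamped.
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector img, int H2, int W2) {
  IntegerVector d = img.attr("dim");
  const int H = d[0], W = d[1], C = d[2];
  NumericVector out((size_t)H2 * W2 * C);
  out.attr("dim") = IntegerVector::create(H2, W2, C);
  std::vector<int> h0(H2), h1(H2);
  std::vector<double> hf(H2);
  for (int i = 0; i < H2; ++i) {
    double s = (i + 0.5) * (double)H / H2 - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    h0[i] = (int)std::floor(s);
    h1[i] = clampi(h0[i] + 1, 0, H - 1);
    hf[i] = s - h0[i];
  }
  std::vector<int> w0(W2), w1(W2);
  std::vector<double> wf(W2);
  for (int j = 0; j < W2; ++j) {
    double s = (j + 0.5) * (double)W / W2 - 0.5;
    if (s < 0) s = 0;
    if (s > W - 1) s = W - 1;
    w0[j] = (int)std::floor(s);
    w1[j] = clampi(w0[j] + 1, 0, W - 1);
    wf[j] = s - w0[j];
  }
  const double* ip = img.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* plane = ip + (size_t)H * W * c;
    double* oplane = op + (size_t)H2 * W2 * c;
    for (int j = 0; j < W2; ++j) {
      const double* cA = plane + (size_t)H * w0[j];
      const double* cB = plane + (size_t)H * w1[j];
      const double fw = wf[j];
      double* ocol = oplane + (size_t)H2 * j;
      for (int i = 0; i < H2; ++i) {
        const double fh = hf[i];
        const double top = cA[h0[i]] * (1 - fw) + cB[h0[i]] * fw;
        const double bot = cA[h1[i]] * (1 - fw) + cB[h1[i]] * fw;
        ocol[i] = top * (1 - fh) + bot * fh;
      }
    }
  }
  return out;
}

// Nearest-neighbour resize for integer label masks (same center mapping).
// [[Rcpp::export]]
IntegerMatrix cpp_resize_nearest(IntegerMatrix lab, int H2, int W2) {
  const int H = lab.nrow(), W = lab.ncol();
  IntegerMatrix out(H2, W2);
  std::vector<int> hs(H2), ws(W2);
  for (int i = 0; i < H2; ++i)
    hs[i] = clampi((int)std::floor((i + 0.5) * (double)H / H2), 0, H - 1);
  for (int j = 0; j < W2; ++j)
    ws[j] = clampi((int)std::floor((j + 0.5) * (double)W / W2), 0, W - 1);
  for (int j = 0; j < W2; ++j)
    for (int i = 0; i < H2; ++i) out(i, j) = lab(hs[i], ws[j]);
  return out;
}

// Scanline polygon fill with the pixel-center rule: pixel (row i, col j),
// center (j + 0.5, i + 0.5), gets `value` when the center lies strictly
// inside the polygon (even-odd rule).  Polygons are filled in list order,
// later fills overwriting earlier ones (last drawn wins).
// verts: n x 2 matrix of (x, y), already scaled to the target spacing.
// [[Rcpp::export]]
IntegerMatrix cpp_rasterize(int H, int W, List polys, IntegerVector values,
                            int background) {
  IntegerMatrix lab(H, W);
  std::fill(lab.begin(), lab.end(), background);
  const int np = polys.size();
  for (int p = 0; p < np; ++p) {
    NumericMatrix v = polys[p];
    const int nv = v.nrow();
    const int val = values[p];
    double ymin = v(0, 1), ymax = v(0, 1);
    for (int a = 1; a < nv; ++a) {
      ymin = std::min(ymin, v(a, 1));
      ymax = std::max(ymax, v(a, 1));
    }
    const int i_lo = std::max(0, (int)std::ceil(ymin - 0.5));
    const int i_hi = std::min(H - 1, (int)std::floor(ymax - 0.5));
    std::vector<double> xs;
    for (int i = i_lo; i <= i_hi; ++i) {
      const double yc = i + 0.5;
      xs.clear();
      for (int a = 0; a < nv; ++a) {
        const int bdx = (a + 1) % nv;
        const double y1 = v(a, 1), y2 = v(bdx, 1);
        if ((y1 <= yc) != (y2 <= yc)) {
          const double t = (yc - y1) / (y2 - y1);
          xs.push_back(v(a, 0) + t * (v(bdx, 0) - v(a, 0)));
        }
      }
      std::sort(xs.begin(), xs.end());
      for (size_t q = 0; q + 1 < xs.size(); q += 2) {
        int j_lo = (int)std::floor(xs[q] - 0.5) + 1;
        int j_hi = (int)std::ceil(xs[q + 1] - 0.5) - 1;
        j_lo = std::max(j_lo, 0);
        j_hi = std::min(j_hi, W - 1);
        for (int j = j_lo; j <= j_hi; ++j) lab(i, j) = val;
      }
    }
  }
  return lab;
}

// Batchnorm + ReLU over the channel dim of (H,W,C,N), training mode:
// batch statistics, y = relu(gamma * (x - mu)/sqrt(var + eps) + beta).
// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                double eps) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t plane = (size_t)H * W;
  const double n = (double)plane * N;
  NumericVector y((size_t)H * W * C * N);
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector mu(C), var(C);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c) {
    double s = 0, ss = 0;
    for (int nn = 0; nn < N; ++nn) {
      const double* xc = xp + plane * (c + (size_t)C * nn);
      for (size_t i = 0; i < plane; ++i) {
        s += xc[i];
        ss += xc[i] * xc[i];
      }
    }
    const double m = s / n;
    const double v = ss / n - m * m;
    mu[c] = m;
    var[c] = v > 0 ? v : 0;
    const double invstd = 1.0 / std::sqrt(var[c] + eps);
    const double a = gamma[c] * invstd;
    const double b = beta[c] - m * a;
    for (int nn = 0; nn < N; ++nn) {
      const double* xc = xp + plane * (c + (size_t)C * nn);
      double* yc = yp + plane * (c + (size_t)C * nn);
      for (size_t i = 0; i < plane; ++i) {
        const double val = a * xc[i] + b;
        yc[i] = val > 0 ? val : 0.0;
      }
    }
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["var"] = var);
}

// inference mode using running statistics
// [[Rcpp::export]]
NumericVector cpp_bn_infer(NumericVector x, NumericVector gamma,
                           NumericVector beta, NumericVector mean,
                           NumericVector var, double eps) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t plane = (size_t)H * W;
  NumericVector y((size_t)H * W * C * N);
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c) {
    const double a = gamma[c] / std::sqrt(var[c] + eps);
    const double b = beta[c] - mean[c] * a;
    for (int nn = 0; nn < N; ++nn) {
      const double* xc = xp + plane * (c + (size_t)C * nn);
      double* yc = yp + plane * (c + (size_t)C * nn);
      for (size_t i = 0; i < plane; ++i) {
        const double val = a * xc[i] + b;
        yc[i] = val > 0 ? val : 0.0;
      }
    }
  }
  return y;
}

// backward through training-mode batchnorm + ReLU; x is the node input,
// y the forward output (ReLU mask), mu/var the cached batch statistics.
// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, NumericVector y, NumericVector dy,
                NumericVector gamma, NumericVector mu, NumericVector var,
                double eps) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t plane = (size_t)H * W;
  const double n = (double)plane * N;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dgamma(C), dbeta(C);
  const double* xp = x.begin();
  const double* yp = y.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  for (int c = 0; c < C; ++c) {
    const double invstd = 1.0 / std::sqrt(var[c] + eps);
    const double m = mu[c];
    double s1 = 0, s2 = 0;
    for (int nn = 0; nn < N; ++nn) {
      const size_t off = plane * (c + (size_t)C * nn);
      const double* xc = xp + off;
      const double* yc = yp + off;
      const double* dyc = dyp + off;
      for (size_t i = 0; i < plane; ++i) {
        const double g = yc[i] > 0 ? dyc[i] : 0.0;
        s1 += g;
        s2 += g * (xc[i] - m) * invstd;
      }
    }
    dbeta[c] = s1;
    dgamma[c] = s2;
    const double k1 = s1 / n, k2 = s2 / n;
    const double a = gamma[c] * invstd;
    for (int nn = 0; nn < N; ++nn) {
      const size_t off = plane * (c + (size_t)C * nn);
      const double* xc = xp + off;
      const double* yc = yp + off;
      const double* dyc = dyp + off;
      double* dxc = dxp + off;
      for (size_t i = 0; i < plane; ++i) {
        const double g = yc[i] > 0 ? dyc[i] : 0.0;
        const double xhat = (xc[i] - m) * invstd;
        dxc[i] = a * (g - k1 - xhat * k2);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dgamma, _["db"] = dbeta);
}

// Separable Gaussian blur with reflect-101 borders; img (H,W,C).
// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector img, double sigma) {
  IntegerVector d = img.attr("dim");
  const int H = d[0], W = d[1], C = d[2];
  const int r = std::max(1, (int)std::ceil(2.5 * sigma));
  std::vector<double> ker(2 * r + 1);
  double s = 0;
  for (int t = -r; t <= r; ++t) {
    ker[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += ker[t + r];
  }
  for (double& kv : ker) kv /= s;
  auto reflect = [](int i, int n) {
    if (n == 1) return 0;
    const int period = 2 * n - 2;
    int m = i % period;
    if (m < 0) m += period;
    return m < n ? m : period - m;
  };
  NumericVector out((size_t)H * W * C);
  out.attr("dim") = IntegerVector::create(H, W, C);
  std::vector<double> tmp((size_t)H * W);
  const double* ip = img.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* plane = ip + (size_t)H * W * c;
    // vertical pass
    for (int j = 0; j < W; ++j) {
      const double* col = plane + (size_t)H * j;
      double* tcol = tmp.data() + (size_t)H * j;
      for (int i = 0; i < H; ++i) {
        double acc = 0;
        for (int t = -r; t <= r; ++t) acc += ker[t + r] * col[reflect(i + t, H)];
        tcol[i] = acc;
      }
    }
    // horizontal pass
    double* oplane = op + (size_t)H * W * c;
    for (int j = 0; j < W; ++j) {
      double* ocol = oplane + (size_t)H * j;
      for (int i = 0; i < H; ++i) {
        double acc = 0;
        for (int t = -r; t <= r; ++t)
          acc += ker[t + r] * tmp[(size_t)H * reflect(j + t, W) + i];
        ocol[i] = acc;
      }
    }
  }
  return out;
}
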