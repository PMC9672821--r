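// Low-level kernels for the 2D UNet and 1D temporal blocks.
//
// Tensor layouts (column-major R arrays):
//   2D feature maps: (H, W, C, N)  -- N = slices in the batch
//   1D curve stacks: (T, C, V)     -- V = voxels in the batch
// Convolution weights are plain matrices of shape (kh*kw*Cin, Cout) for 2D
// and (k*Cin, Cout) for 1D. Patch rows are ordered (ki, kj, c) / (ki, c)
// so that the im2col scatter runs along contiguous memory; the patch
// matrices are kept transposed (pixels x patch) for the same reason.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// transposed im2col: rows = output pixels (io, jo, n), cols = patch
// elements (ki, kj, c); symmetric zero padding p
static arma::mat im2colT2d(const double *xp, int H, int W, int C, int N,
                           int k, int p) {
  const int Ho = H + 2 * p - k + 1;
  const int Wo = W + 2 * p - k + 1;
  arma::mat out((size_t)Ho * Wo * N, (size_t)C * k * k, arma::fill::none);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        double *op = out.colptr(ki + k * ((size_t)kj + (size_t)k * c));
        const int i0 = std::max(0, p - ki);
        const int i1 = std::min(Ho, H + p - ki);
        for (int n = 0; n < N; ++n) {
          const double *xn = xp + (size_t)H * W * (c + (size_t)C * n);
          double *on = op + (size_t)Ho * Wo * n;
          for (int jo = 0; jo < Wo; ++jo) {
            const int j = jo + kj - p;
            double *row = on + (size_t)Ho * jo;
            if (j < 0 || j >= W || i1 <= i0) {
              std::memset(row, 0, (size_t)Ho * sizeof(double));
              continue;
            }
            if (i0 > 0) std::memset(row, 0, (size_t)i0 * sizeof(double));
            if (i1 < Ho)
              std::memset(row + i1, 0, (size_t)(Ho - i1) * sizeof(double));
            std::memcpy(row + i0, xn + (size_t)H * j + (i0 + ki - p),
                        (size_t)(i1 - i0) * sizeof(double));
          }
        }
      }
  return out;
}

// scatter-add the transposed patch gradients back onto the input grid
static void col2imT2d(const arma::mat &cols, double *dp, int H, int W, int C,
                      int N, int k, int p) {
  const int Ho = H + 2 * p - k + 1;
  const int Wo = W + 2 * p - k + 1;
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const double *cp = cols.colptr(ki + k * ((size_t)kj + (size_t)k * c));
        for (int n = 0; n < N; ++n) {
          double *dn = dp + (size_t)H * W * (c + (size_t)C * n);
          const double *cn = cp + (size_t)Ho * Wo * n;
          for (int jo = 0; jo < Wo; ++jo) {
            const int j = jo + kj - p;
            if (j < 0 || j >= W) continue;
            const int i0 = std::max(0, p - ki);
            const int i1 = std::min(Ho, H + p - ki);
            double *dst = dn + (size_t)H * j + (i0 + ki - p);
            const double *src = cn + (size_t)Ho * jo + i0;
            for (int i = 0; i < i1 - i0; ++i) dst[i] += src[i];
          }
        }
      }
}

// [[Rcpp::export(name = ".nnConv2Fw")]]
NumericVector nnConv2Fw(NumericVector x, NumericMatrix w, NumericVector b,
                        int k, int pad) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = H + 2 * pad - k + 1, Wo = W + 2 * pad - k + 1;
  const int Cout = w.ncol();
  arma::mat wm(w.begin(), w.nrow(), w.ncol(), false);
  arma::mat Xt = im2colT2d(x.begin(), H, W, C, N, k, pad);
  arma::mat Yt = Xt * wm;  // (Ho*Wo*N) x Cout
  NumericVector out(no_init((size_t)Ho * Wo * Cout * N));
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  double *op = out.begin();
  for (int co = 0; co < Cout; ++co) {
    const double *yc = Yt.colptr(co);
    const double bc = b[co];
    for (int n = 0; n < N; ++n) {
      double *on = op + (size_t)Ho * Wo * (co + (size_t)Cout * n);
      const double *yn = yc + (size_t)Ho * Wo * n;
      for (size_t px = 0; px < (size_t)Ho * Wo; ++px) on[px] = yn[px] + bc;
    }
  }
  return out;
}

// reshape dy (Ho,Wo,Cout,N) into (Ho*Wo*N) x Cout
static arma::mat dyT2d(const double *dp, int Ho, int Wo, int Cout, int N) {
  arma::mat dYt((size_t)Ho * Wo * N, Cout, arma::fill::none);
  for (int co = 0; co < Cout; ++co) {
    double *yc = dYt.colptr(co);
    for (int n = 0; n < N; ++n)
      std::memcpy(yc + (size_t)Ho * Wo * n,
                  dp + (size_t)Ho * Wo * (co + (size_t)Cout * n),
                  (size_t)Ho * Wo * sizeof(double));
  }
  return dYt;
}

// [[Rcpp::export(name = ".nnConv2Bw")]]
List nnConv2Bw(NumericVector x, NumericMatrix w, NumericVector dy, int k,
               int pad) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = H + 2 * pad - k + 1, Wo = W + 2 * pad - k + 1;
  const int Cout = w.ncol();
  arma::mat wm(w.begin(), w.nrow(), w.ncol(), false);
  arma::mat dYt = dyT2d(dy.begin(), Ho, Wo, Cout, N);
  arma::mat Xt = im2colT2d(x.begin(), H, W, C, N, k, pad);
  arma::mat dW = Xt.t() * dYt;
  arma::rowvec db = arma::sum(dYt, 0);
  arma::mat dXt = dYt * wm.t();  // (Ho*Wo*N) x (C*k*k)
  NumericVector dx(x.size());
  dx.attr("dim") = d;
  col2imT2d(dXt, dx.begin(), H, W, C, N, k, pad);
  return List::create(_["dx"] = dx, _["dw"] = wrap(dW),
                      _["db"] = wrap(arma::vec(db.t())));
}

// 2x2 max pooling, stride 2; records flat argmax indices for backward
// [[Rcpp::export(name = ".nnPool2Fw")]]
List nnPool2Fw(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(no_init((size_t)Ho * Wo * C * N));
  IntegerVector idx(no_init((size_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double *xp = x.begin();
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const size_t ibase = (size_t)H * W * cn, obase = (size_t)Ho * Wo * cn;
    for (int jo = 0; jo < Wo; ++jo)
      for (int io = 0; io < Ho; ++io) {
        size_t best = ibase + (size_t)(2 * io) + (size_t)H * (2 * jo);
        double bv = xp[best];
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const size_t ii =
                ibase + (size_t)(2 * io + di) + (size_t)H * (2 * jo + dj);
            if (xp[ii] > bv) { bv = xp[ii]; best = ii; }
          }
        y[obase + io + (size_t)Ho * jo] = bv;
        idx[obase + io + (size_t)Ho * jo] = (int)best;
      }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".nnPool2Bw")]]
NumericVector nnPool2Bw(NumericVector dy, IntegerVector idx,
                        IntegerVector dimIn) {
  size_t n = (size_t)dimIn[0] * dimIn[1] * dimIn[2] * dimIn[3];
  NumericVector dx(n);
  dx.attr("dim") = dimIn;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  return dx;
}

// transposed im2col over time for (T, C, V); rows = (to, v), cols =
// (ki, c). causal: left zero padding of d*(k-1), output length T;
// valid: output length (T - dil*(k-1) - 1) / stride + 1, input position
// stride*to + dil*ki.
static int conv1OutLen(int T, int k, int dil, int stride, bool causal) {
  return causal ? T : (T - dil * (k - 1) - 1) / stride + 1;
}

static arma::mat im2colT1d(const double *xp, int T, int C, int V, int k,
                           int dil, bool causal, int stride) {
  const int To = conv1OutLen(T, k, dil, stride, causal);
  if (!causal && stride > 1) {
    // strided valid convolution (dependency-cone evaluation)
    arma::mat out((size_t)To * V, (size_t)C * k, arma::fill::none);
    for (int c = 0; c < C; ++c)
      for (int ki = 0; ki < k; ++ki) {
        double *op = out.colptr(ki + (size_t)k * c);
        for (int v = 0; v < V; ++v) {
          const double *xv = xp + (size_t)T * (c + (size_t)C * v);
          double *col = op + (size_t)To * v;
          for (int to = 0; to < To; ++to) col[to] = xv[stride * to + dil * ki];
        }
      }
    return out;
  }
  arma::mat out((size_t)To * V, (size_t)C * k, arma::fill::none);
  for (int c = 0; c < C; ++c)
    for (int ki = 0; ki < k; ++ki) {
      double *op = out.colptr(ki + (size_t)k * c);
      const int off = causal ? dil * (ki - (k - 1)) : dil * ki;
      const int t0 = std::max(0, std::min(To, -off));
      const int t1 = std::max(t0, std::min(To, T - off));
      for (int v = 0; v < V; ++v) {
        double *col = op + (size_t)To * v;
        if (t0 > 0) std::memset(col, 0, (size_t)t0 * sizeof(double));
        if (t1 < To)
          std::memset(col + t1, 0, (size_t)(To - t1) * sizeof(double));
        if (t1 > t0)
          std::memcpy(col + t0,
                      xp + (size_t)T * (c + (size_t)C * v) + (t0 + off),
                      (size_t)(t1 - t0) * sizeof(double));
      }
    }
  return out;
}

// [[Rcpp::export(name = ".nnConv1Fw")]]
NumericVector nnConv1Fw(NumericVector x, NumericMatrix w, NumericVector b,
                        int k, int dil, bool causal, int stride = 1) {
  IntegerVector d = x.attr("dim");
  const int T = d[0], C = d[1], V = d[2];
  const int To = conv1OutLen(T, k, dil, stride, causal);
  const int Cout = w.ncol();
  arma::mat wm(w.begin(), w.nrow(), w.ncol(), false);
  arma::mat Xt = im2colT1d(x.begin(), T, C, V, k, dil, causal, stride);
  arma::mat Yt = Xt * wm;  // (To*V) x Cout
  NumericVector out(no_init((size_t)To * Cout * V));
  out.attr("dim") = IntegerVector::create(To, Cout, V);
  double *op = out.begin();
  for (int co = 0; co < Cout; ++co) {
    const double *yc = Yt.colptr(co);
    const double bc = b[co];
    for (int v = 0; v < V; ++v) {
      double *ov = op + (size_t)To * (co + (size_t)Cout * v);
      const double *yv = yc + (size_t)To * v;
      for (int t = 0; t < To; ++t) ov[t] = yv[t] + bc;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".nnConv1Bw")]]
List nnConv1Bw(NumericVector x, NumericMatrix w, NumericVector dy, int k,
               int dil, bool causal, int stride = 1) {
  IntegerVector d = x.attr("dim");
  const int T = d[0], C = d[1], V = d[2];
  const int To = conv1OutLen(T, k, dil, stride, causal);
  const int Cout = w.ncol();
  arma::mat wm(w.begin(), w.nrow(), w.ncol(), false);
  arma::mat dYt((size_t)To * V, Cout, arma::fill::none);
  const double *dp = dy.begin();
  for (int co = 0; co < Cout; ++co) {
    double *yc = dYt.colptr(co);
    for (int v = 0; v < V; ++v)
      std::memcpy(yc + (size_t)To * v,
                  dp + (size_t)To * (co + (size_t)Cout * v),
                  (size_t)To * sizeof(double));
  }
  arma::mat Xt = im2colT1d(x.begin(), T, C, V, k, dil, causal, stride);
  arma::mat dW = Xt.t() * dYt;
  arma::rowvec db = arma::sum(dYt, 0);
  arma::mat dXt = dYt * wm.t();  // (To*V) x (C*k)
  NumericVector dx(x.size());
  dx.attr("dim") = d;
  double *dxp = dx.begin();
  if (!causal && stride > 1) {
    for (int c = 0; c < C; ++c)
      for (int ki = 0; ki < k; ++ki) {
        const double *cp = dXt.colptr(ki + (size_t)k * c);
        for (int v = 0; v < V; ++v) {
          double *dv = dxp + (size_t)T * (c + (size_t)C * v);
          const double *src = cp + (size_t)To * v;
          for (int to = 0; to < To; ++to) dv[stride * to + dil * ki] += src[to];
        }
      }
  } else {
    for (int c = 0; c < C; ++c)
      for (int ki = 0; ki < k; ++ki) {
        const double *cp = dXt.colptr(ki + (size_t)k * c);
        const int off = causal ? dil * (ki - (k - 1)) : dil * ki;
        const int t0 = std::max(0, -off);
        const int t1 = std::min(To, T - off);
        if (t1 <= t0) continue;
        for (int v = 0; v < V; ++v) {
          double *dst = dxp + (size_t)T * (c + (size_t)C * v) + (t0 + off);
          const double *src = cp + (size_t)To * v + t0;
          for (int t = 0; t < t1 - t0; ++t) dst[t] += src[t];
        }
      }
  }
  return List::create(_["dx"] = dx, _["dw"] = wrap(dW),
                      _["db"] = wrap(arma::vec(db.t())));
}

// temporal max pooling by a factor of two (floor semantics)
// [[Rcpp::export(name = ".nnPool1Fw")]]
List nnPool1Fw(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int T = d[0], C = d[1], V = d[2];
  const int To = T / 2;
  NumericVector y(no_init((size_t)To * C * V));
  IntegerVector idx(no_init((size_t)To * C * V));
  y.attr("dim") = IntegerVector::create(To, C, V);
  const double *xp = x.begin();
  for (size_t cv = 0; cv < (size_t)C * V; ++cv) {
    const size_t ib = (size_t)T * cv, ob = (size_t)To * cv;
    for (int to = 0; to < To; ++to) {
      size_t a = ib + 2 * to, bq = a + 1;
      const bool takeA = xp[a] >= xp[bq];
      y[ob + to] = takeA ? xp[a] : xp[bq];
      idx[ob + to] = (int)(takeA ? a : bq);
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".nnPool1Bw")]]
NumericVector nnPool1Bw(NumericVector dy, IntegerVector idx,
                        IntegerVector dimIn) {
  size_t n = (size_t)dimIn[0] * dimIn[1] * dimIn[2];
  NumericVector dx(n);
  dx.attr("dim") = dimIn;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  return dx;
}

// single-pass ReLU (the R idiom makes several large temporaries)
// [[Rcpp::export(name = ".nnRelu")]]
NumericVector nnRelu(NumericVector x) {
  NumericVector y(no_init(x.size()));
  y.attr("dim") = x.attr("dim");
  const double *xp = x.begin();
  double *yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) yp[i] = xp[i] > 0 ? xp[i] : 0;
  return y;
}

// [[Rcpp::export(name = ".nnReluBw")]]
NumericVector nnReluBw(NumericVector dy, NumericVector y) {
  NumericVector dx(no_init(dy.size()));
  dx.attr("dim") = dy.attr("dim");
  const double *dp = dy.begin(), *yp = y.begin();
  double *op = dx.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) op[i] = yp[i] > 0 ? dp[i] : 0;
  return dx;
}
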