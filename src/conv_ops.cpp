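// Low-level convolution primitives for the proximity-regression network.
// Layout conventions (match R arrays, column-major):
//   activations: dim (H, W, C, N)
//   conv weights: matrix (k*k*Cin, Cout), row index = kh + k*(kw + k*c)
//   tconv (kernel = stride = s) weights: matrix (Cin, s*s*Cout),
//     column index = si + s*sj + s*s*c
// Spatial padding (pt, pl) is applied on the top/left only; out-of-range
// taps read zero. Output size is supplied by the caller.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void im2col_one(const double* x, int H, int W, int C,
                              int k, int stride, int pt, int pl,
                              int Ho, int Wo, arma::mat& cols) {
  // cols: (k*k*C, Ho*Wo); fill column-contiguously for cache locality
  const size_t nr = cols.n_rows;
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      double* dst = cols.colptr(0) + nr * ((size_t)i + (size_t)Ho * j);
      int hbase = i * stride - pt, wbase = j * stride - pl;
      for (int c = 0; c < C; ++c) {
        const double* xc = x + (size_t)H * W * c;
        for (int kw = 0; kw < k; ++kw) {
          int w0 = wbase + kw;
          if (w0 < 0 || w0 >= W) {
            for (int kh = 0; kh < k; ++kh) *dst++ = 0.0;
            continue;
          }
          const double* xcw = xc + (size_t)H * w0;
          for (int kh = 0; kh < k; ++kh) {
            int h0 = hbase + kh;
            *dst++ = (h0 >= 0 && h0 < H) ? xcw[h0] : 0.0;
          }
        }
      }
    }
  }
}

static inline void col2im_one(const arma::mat& cols, int H, int W, int C,
                              int k, int stride, int pt, int pl,
                              int Ho, int Wo, double* gx) {
  const size_t nr = cols.n_rows;
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      const double* src =
        cols.colptr(0) + nr * ((size_t)i + (size_t)Ho * j);
      int hbase = i * stride - pt, wbase = j * stride - pl;
      for (int c = 0; c < C; ++c) {
        double* gc = gx + (size_t)H * W * c;
        for (int kw = 0; kw < k; ++kw) {
          int w0 = wbase + kw;
          if (w0 < 0 || w0 >= W) { src += k; continue; }
          double* gcw = gc + (size_t)H * w0;
          for (int kh = 0; kh < k; ++kh) {
            int h0 = hbase + kh;
            if (h0 >= 0 && h0 < H) gcw[h0] += *src;
            ++src;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv_fwd_cpp(NumericVector x, NumericMatrix w, NumericVector b,
                           int k, int stride, int pt, int pl, int Ho, int Wo) {
  IntegerVector dim = x.attr("dim");
  int H = dim[0], W = dim[1], C = dim[2], N = dim[3];
  int Cout = w.ncol();
  arma::mat wm(w.begin(), w.nrow(), w.ncol(), false);
  arma::rowvec bv(b.begin(), b.size(), false);
  NumericVector out((size_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat cols(k * k * C, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (size_t)H * W * C * n, H, W, C,
               k, stride, pt, pl, Ho, Wo, cols);
    arma::mat y(out.begin() + (size_t)Ho * Wo * Cout * n,
                (size_t)Ho * Wo, Cout, false, true);
    y = cols.t() * wm;
    y.each_row() += bv;
  }
  return out;
}

// [[Rcpp::export]]
List conv_bwd_cpp(NumericVector x, NumericMatrix w, NumericVector gy,
                  int k, int stride, int pt, int pl) {
  IntegerVector dim = x.attr("dim");
  int H = dim[0], W = dim[1], C = dim[2], N = dim[3];
  IntegerVector dimy = gy.attr("dim");
  int Ho = dimy[0], Wo = dimy[1], Cout = dimy[2];
  arma::mat wm(w.begin(), w.nrow(), w.ncol(), false);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = dim;
  arma::mat gw(w.nrow(), w.ncol(), arma::fill::zeros);
  arma::rowvec gb(Cout, arma::fill::zeros);
  arma::mat cols(k * k * C, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (size_t)H * W * C * n, H, W, C,
               k, stride, pt, pl, Ho, Wo, cols);
    arma::mat gyn(gy.begin() + (size_t)Ho * Wo * Cout * n,
                  (size_t)Ho * Wo, Cout, false, true);
    gw += cols * gyn;
    gb += arma::sum(gyn, 0);
    arma::mat gcols = wm * gyn.t();
    col2im_one(gcols, H, W, C, k, stride, pt, pl, Ho, Wo,
               gx.begin() + (size_t)H * W * C * n);
  }
  return List::create(_["gx"] = gx,
                      _["gw"] = NumericMatrix(w.nrow(), w.ncol(), gw.begin()),
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// Transposed convolution with kernel = stride = s ("sub-pixel" upsampling):
// each input pixel emits an s x s output block; blocks do not overlap.
// [[Rcpp::export]]
NumericVector tconv_fwd_cpp(NumericVector x, NumericMatrix w, NumericVector b,
                            int s) {
  IntegerVector dim = x.attr("dim");
  int H = dim[0], W = dim[1], C = dim[2], N = dim[3];
  int Cout = w.ncol() / (s * s);
  int Ho = H * s, Wo = W * s;
  arma::mat wm(w.begin(), w.nrow(), w.ncol(), false);
  NumericVector out((size_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat xm(const_cast<double*>(x.begin()) + (size_t)H * W * C * n,
                 (size_t)H * W, C, false, true);
    arma::mat ycols = xm * wm;  // (H*W, s*s*Cout)
    double* o = out.begin() + (size_t)Ho * Wo * Cout * n;
    for (int c = 0; c < Cout; ++c) {
      double bc = b[c];
      double* oc = o + (size_t)Ho * Wo * c;
      for (int sj = 0; sj < s; ++sj) {
        for (int si = 0; si < s; ++si) {
          const double* src = ycols.colptr(si + s * sj + s * s * c);
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              oc[(size_t)(i * s + si) + (size_t)Ho * (j * s + sj)] =
                src[i + (size_t)H * j] + bc;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List tconv_bwd_cpp(NumericVector x, NumericMatrix w, NumericVector gy, int s) {
  IntegerVector dim = x.attr("dim");
  int H = dim[0], W = dim[1], C = dim[2], N = dim[3];
  int Cout = w.ncol() / (s * s);
  int Ho = H * s, Wo = W * s;
  arma::mat wm(w.begin(), w.nrow(), w.ncol(), false);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = dim;
  arma::mat gw(w.nrow(), w.ncol(), arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  arma::mat gycols((size_t)H * W, s * s * Cout);
  for (int n = 0; n < N; ++n) {
    const double* g = gy.begin() + (size_t)Ho * Wo * Cout * n;
    for (int c = 0; c < Cout; ++c) {
      const double* gc = g + (size_t)Ho * Wo * c;
      for (int sj = 0; sj < s; ++sj) {
        for (int si = 0; si < s; ++si) {
          double* dst = gycols.colptr(si + s * sj + s * s * c);
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              dst[i + (size_t)H * j] =
                gc[(size_t)(i * s + si) + (size_t)Ho * (j * s + sj)];
        }
      }
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p) gb[c] += gc[p];
    }
    arma::mat xm(const_cast<double*>(x.begin()) + (size_t)H * W * C * n,
                 (size_t)H * W, C, false, true);
    gw += xm.t() * gycols;
    arma::mat gxm(gx.begin() + (size_t)H * W * C * n,
                  (size_t)H * W, C, false, true);
    gxm += gycols * wm.t();
  }
  return List::create(_["gx"] = gx,
                      _["gw"] = NumericMatrix(w.nrow(), w.ncol(), gw.begin()),
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// ---- batch norm + ELU kernels (hot path helpers) -------------------------

// [[Rcpp::export]]
List bn_stats_cpp(NumericVector x) {
  IntegerVector dim = x.attr("dim");
  int H = dim[0], W = dim[1], C = dim[2], N = dim[3];
  size_t hw = (size_t)H * W;
  NumericVector m(C), v(C);
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    double mu = s / (hw * N);
    m[c] = mu;
    double var = s2 / (hw * N) - mu * mu;
    v[c] = var > 0 ? var : 0;
  }
  return List::create(_["mean"] = m, _["var"] = v);
}

// [[Rcpp::export]]
List bn_fwd_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector m, NumericVector invstd) {
  IntegerVector dim = x.attr("dim");
  int H = dim[0], W = dim[1], C = dim[2], N = dim[3];
  size_t hw = (size_t)H * W;
  NumericVector y(x.size()), xhat(x.size());
  y.attr("dim") = dim; xhat.attr("dim") = dim;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + hw * (c + (size_t)C * n);
      double* py = y.begin() + hw * (c + (size_t)C * n);
      double* ph = xhat.begin() + hw * (c + (size_t)C * n);
      double mu = m[c], is = invstd[c], g = gamma[c], b = beta[c];
      for (size_t i = 0; i < hw; ++i) {
        double h = (p[i] - mu) * is;
        ph[i] = h;
        py[i] = g * h + b;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat);
}

// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector xhat, NumericVector gamma,
                NumericVector invstd, NumericVector gy, bool train) {
  IntegerVector dim = xhat.attr("dim");
  int H = dim[0], W = dim[1], C = dim[2], N = dim[3];
  size_t hw = (size_t)H * W;
  double count = (double)hw * N;
  NumericVector ggamma(C), gbeta(C), gx(xhat.size());
  gx.attr("dim") = dim;
  std::vector<double> mg(C, 0.0), mgx(C, 0.0);
  for (int c = 0; c < C; ++c) {
    double sg = 0.0, sgx = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* ph = xhat.begin() + hw * (c + (size_t)C * n);
      const double* pg = gy.begin() + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) {
        sg += pg[i];
        sgx += pg[i] * ph[i];
      }
    }
    gbeta[c] = sg;
    ggamma[c] = sgx;
    mg[c] = gamma[c] * sg / count;
    mgx[c] = gamma[c] * sgx / count;
  }
  for (int c = 0; c < C; ++c) {
    double g = gamma[c], is = invstd[c];
    for (int n = 0; n < N; ++n) {
      const double* ph = xhat.begin() + hw * (c + (size_t)C * n);
      const double* pg = gy.begin() + hw * (c + (size_t)C * n);
      double* px = gx.begin() + hw * (c + (size_t)C * n);
      if (train)
        for (size_t i = 0; i < hw; ++i)
          px[i] = is * (g * pg[i] - mg[c] - ph[i] * mgx[c]);
      else
        for (size_t i = 0; i < hw; ++i)
          px[i] = is * g * pg[i];
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma,
                      _["gbeta"] = gbeta);
}

// [[Rcpp::export]]
NumericVector elu_fwd_cpp(NumericVector x, double alpha) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i)
    y[i] = x[i] > 0 ? x[i] : alpha * std::expm1(x[i]);
  return y;
}

// [[Rcpp::export]]
NumericVector elu_bwd_cpp(NumericVector y, double alpha, NumericVector gy) {
  NumericVector g(y.size());
  g.attr("dim") = y.attr("dim");
  for (R_xlen_t i = 0; i < y.size(); ++i)
    g[i] = y[i] > 0 ? gy[i] : gy[i] * (y[i] + alpha);
  return g;
}
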