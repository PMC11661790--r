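// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Layout conventions
// ------------------
// Activations: R array (H, W, C, N), column-major, H fastest.
// Conv weights: matrix (9 * Cin, Cout); row index = kx + 3*ky + 9*c with
// kernel offsets kx, ky in {0,1,2} meaning spatial shifts {-1,0,+1}
// (matches an R array of dim c(3, 3, Cin, Cout) flattened column-major).
// All convolutions are 3x3, stride 1, zero-padded ("same").

static arma::mat im2col3x3(const double *x, int H, int W, int C, int N) {
  arma::mat M((size_t)H * W * N, (size_t)9 * C);
  const size_t plane = (size_t)H * W;
  for (int c = 0; c < C; ++c)
    for (int ky = 0; ky < 3; ++ky)
      for (int kx = 0; kx < 3; ++kx) {
        int dx = kx - 1, dy = ky - 1;
        double *col = M.colptr((size_t)c * 9 + ky * 3 + kx);
        for (int n = 0; n < N; ++n) {
          const double *xc = x + plane * ((size_t)C * n + c);
          double *dst = col + plane * n;
          for (int w = 0; w < W; ++w) {
            int ws = w + dy;
            if (ws < 0 || ws >= W) {
              std::fill(dst + (size_t)w * H, dst + (size_t)(w + 1) * H, 0.0);
              continue;
            }
            const double *src = xc + (size_t)ws * H;
            double *d = dst + (size_t)w * H;
            int h0 = std::max(0, -dx), h1 = std::min(H, H - dx);
            for (int h = 0; h < h0; ++h) d[h] = 0.0;
            for (int h = h0; h < h1; ++h) d[h] = src[h + dx];
            for (int h = h1; h < H; ++h) d[h] = 0.0;
          }
        }
      }
  return M;
}

// Scatter-add of a column matrix P (HWN x 9C) back onto an input gradient.
static void col2im3x3(const arma::mat &P, double *gx, int H, int W, int C,
                      int N) {
  const size_t plane = (size_t)H * W;
  for (int c = 0; c < C; ++c)
    for (int ky = 0; ky < 3; ++ky)
      for (int kx = 0; kx < 3; ++kx) {
        int dx = kx - 1, dy = ky - 1;
        const double *col = P.colptr((size_t)c * 9 + ky * 3 + kx);
        for (int n = 0; n < N; ++n) {
          double *gc = gx + plane * ((size_t)C * n + c);
          const double *srcn = col + plane * n;
          for (int w = 0; w < W; ++w) {
            int ws = w + dy;
            if (ws < 0 || ws >= W) continue;
            double *dstc = gc + (size_t)ws * H;
            const double *s = srcn + (size_t)w * H;
            int h0 = std::max(0, -dx), h1 = std::min(H, H - dx);
            for (int h = h0; h < h1; ++h) dstc[h + dx] += s[h];
          }
        }
      }
}

static IntegerVector adim(const NumericVector &x) {
  return x.attr("dim");
}

// Forward conv. When return_cols is true the im2col matrix is also
// returned so the backward pass can reuse it instead of rebuilding it
// (it is the dominant memory traffic during training).
// [[Rcpp::export]]
List cpp_conv3x3_fw(NumericVector x, NumericVector wmat, NumericVector bias,
                    bool return_cols) {
  IntegerVector d = adim(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Co = bias.size();
  arma::mat M = im2col3x3(x.begin(), H, W, C, N);
  arma::mat Wm(wmat.begin(), (size_t)9 * C, Co, false);
  arma::mat R = M * Wm;
  R.each_row() += arma::rowvec(bias.begin(), Co);
  // permute (HWN, Co) -> (H, W, Co, N)
  NumericVector out((size_t)H * W * Co * N);
  const size_t plane = (size_t)H * W;
  for (int co = 0; co < Co; ++co) {
    const double *src = R.colptr(co);
    for (int n = 0; n < N; ++n)
      std::copy(src + plane * n, src + plane * (n + 1),
                out.begin() + plane * ((size_t)Co * n + co));
  }
  out.attr("dim") = IntegerVector::create(H, W, Co, N);
  if (!return_cols) return List::create(_["out"] = out);
  NumericVector cols(M.begin(), M.end());
  cols.attr("dim") = IntegerVector::create((int)M.n_rows, (int)M.n_cols);
  return List::create(_["out"] = out, _["cols"] = cols);
}

// Returns list(gx, gw, gb). `cols` is the im2col matrix cached by the
// forward pass; `g` the gradient w.r.t. the conv output (pre-activation).
// [[Rcpp::export]]
List cpp_conv3x3_bw(NumericVector cols, IntegerVector xdim,
                    NumericVector wmat, NumericVector g) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector dg = adim(g);
  int Co = dg[2];
  const size_t plane = (size_t)H * W;
  arma::mat Gm((size_t)H * W * N, Co);
  for (int co = 0; co < Co; ++co) {
    double *dst = Gm.colptr(co);
    for (int n = 0; n < N; ++n)
      std::copy(g.begin() + plane * ((size_t)Co * n + co),
                g.begin() + plane * ((size_t)Co * n + co) + plane,
                dst + plane * n);
  }
  arma::mat M(cols.begin(), (size_t)H * W * N, (size_t)9 * C, false);
  arma::mat Wm(wmat.begin(), (size_t)9 * C, Co, false);
  arma::mat gW = M.t() * Gm;
  arma::rowvec gb = arma::sum(Gm, 0);
  arma::mat P = Gm * Wm.t();
  NumericVector gx((size_t)H * W * C * N); // zero-initialised
  col2im3x3(P, gx.begin(), H, W, C, N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector gwv(gW.begin(), gW.end());
  gwv.attr("dim") = IntegerVector::create(9 * C, Co);
  return List::create(_["gx"] = gx, _["gw"] = gwv,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// 2x2 max pooling, stride 2. Returns list(out, argmax) where argmax holds
// 1-based linear indices into x of the winning element.
// [[Rcpp::export]]
List cpp_maxpool2_fw(NumericVector x) {
  IntegerVector d = adim(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector out((size_t)Ho * Wo * C * N);
  IntegerVector arg((size_t)Ho * Wo * C * N);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t base = (size_t)H * W * ((size_t)C * n + c);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          size_t i00 = base + (size_t)(2 * w) * H + 2 * h;
          size_t cand[4] = {i00, i00 + 1, i00 + H, i00 + H + 1};
          size_t best = cand[0];
          for (int k = 1; k < 4; ++k)
            if (x[cand[k]] > x[best]) best = cand[k];
          out[o] = x[best];
          arg[o] = (int)best + 1;
          ++o;
        }
    }
  // reorder: loop above fills (h,w) fastest within (c,n) but output layout
  // must be (Ho, Wo, C, N) with h fastest -- the loop already emits in that
  // order because h is innermost and w next.
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  arg.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bw(NumericVector g, IntegerVector argmax,
                              IntegerVector xdim) {
  size_t ntot = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(ntot);
  for (R_xlen_t i = 0; i < g.size(); ++i) gx[argmax[i] - 1] += g[i];
  gx.attr("dim") = xdim;
  return gx;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export]]
NumericVector cpp_upsample2_fw(NumericVector x) {
  IntegerVector d = adim(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector out((size_t)Ho * Wo * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t bi = (size_t)H * W * ((size_t)C * n + c);
      size_t bo = (size_t)Ho * Wo * ((size_t)C * n + c);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h)
          out[bo + (size_t)w * Ho + h] = x[bi + (size_t)(w / 2) * H + h / 2];
    }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bw(NumericVector g, IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector gx((size_t)H * W * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t bi = (size_t)H * W * ((size_t)C * n + c);
      size_t bo = (size_t)Ho * Wo * ((size_t)C * n + c);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h)
          gx[bi + (size_t)(w / 2) * H + h / 2] += g[bo + (size_t)w * Ho + h];
    }
  gx.attr("dim") = xdim;
  return gx;
}
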