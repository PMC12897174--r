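// Low-level 3D convolution and max-pooling kernels for the attention-fusion
// network. Tensor layout throughout: column-major R arrays with
// dim = (channels, depth, height, width, batch) — channels fastest.
// Convolution weights are passed as a (C_out x K) matrix with the column
// (patch) index ordered channel-fastest, then kernel depth, height, width,
// matching im2col below.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstring>

using namespace Rcpp;

static void im2col3d(const double* x, int C, int D, int H, int W,
                     int KD, int KH, int KW,
                     int sd, int sh, int sw,
                     int pd, int ph, int pw,
                     int OD, int OH, int OW,
                     arma::mat& col) {
  col.zeros();
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      for (int od = 0; od < OD; ++od) {
        const int p = od + OD * (oh + OH * ow);
        double* cp = col.colptr(p);
        for (int zw = 0; zw < KW; ++zw) {
          const int iw = ow * sw - pw + zw;
          if (iw < 0 || iw >= W) continue;
          for (int zh = 0; zh < KH; ++zh) {
            const int ih = oh * sh - ph + zh;
            if (ih < 0 || ih >= H) continue;
            for (int zd = 0; zd < KD; ++zd) {
              const int id = od * sd - pd + zd;
              if (id < 0 || id >= D) continue;
              const int kbase = C * (zd + KD * (zh + KH * zw));
              const double* xp =
                  x + (size_t)C * (id + (size_t)D * (ih + (size_t)H * iw));
              std::memcpy(cp + kbase, xp, C * sizeof(double));
            }
          }
        }
      }
    }
  }
}

static void col2im3d(const arma::mat& col, double* dx,
                     int C, int D, int H, int W,
                     int KD, int KH, int KW,
                     int sd, int sh, int sw,
                     int pd, int ph, int pw,
                     int OD, int OH, int OW) {
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      for (int od = 0; od < OD; ++od) {
        const int p = od + OD * (oh + OH * ow);
        const double* cp = col.colptr(p);
        for (int zw = 0; zw < KW; ++zw) {
          const int iw = ow * sw - pw + zw;
          if (iw < 0 || iw >= W) continue;
          for (int zh = 0; zh < KH; ++zh) {
            const int ih = oh * sh - ph + zh;
            if (ih < 0 || ih >= H) continue;
            for (int zd = 0; zd < KD; ++zd) {
              const int id = od * sd - pd + zd;
              if (id < 0 || id >= D) continue;
              const int kbase = C * (zd + KD * (zh + KH * zw));
              double* xp =
                  dx + (size_t)C * (id + (size_t)D * (ih + (size_t)H * iw));
              for (int c = 0; c < C; ++c) xp[c] += cp[kbase + c];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3d_fwd")]]
NumericVector conv3d_fwd(NumericVector x, IntegerVector xdim,
                         NumericMatrix Wm, NumericVector b,
                         IntegerVector kdim, IntegerVector stride,
                         IntegerVector pad) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3], N = xdim[4];
  const int KD = kdim[0], KH = kdim[1], KW = kdim[2];
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int pd = pad[0], ph = pad[1], pw = pad[2];
  const int OD = (D + 2 * pd - KD) / sd + 1;
  const int OH = (H + 2 * ph - KH) / sh + 1;
  const int OW = (W + 2 * pw - KW) / sw + 1;
  if (OD < 1 || OH < 1 || OW < 1) stop("convolution output has empty dimension");
  const int Cout = Wm.nrow();
  const int K = C * KD * KH * KW;
  if (Wm.ncol() != K) stop("conv weight matrix has %d columns, expected %d",
                           Wm.ncol(), K);
  const int P = OD * OH * OW;
  const size_t sampIn = (size_t)C * D * H * W;
  const size_t sampOut = (size_t)Cout * P;

  NumericVector out((R_xlen_t)(sampOut * N));
  out.attr("dim") = IntegerVector::create(Cout, OD, OH, OW, N);
  arma::mat Wa(Wm.begin(), Cout, K, false, true);
  arma::colvec ba(b.begin(), Cout, false, true);
  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    im2col3d(x.begin() + n * sampIn, C, D, H, W, KD, KH, KW,
             sd, sh, sw, pd, ph, pw, OD, OH, OW, col);
    arma::mat outm(out.begin() + n * sampOut, Cout, P, false, true);
    outm = Wa * col;
    outm.each_col() += ba;
  }
  return out;
}

// [[Rcpp::export(name = ".conv3d_bwd")]]
List conv3d_bwd(NumericVector x, IntegerVector xdim,
                NumericMatrix Wm, NumericVector dout,
                IntegerVector kdim, IntegerVector stride, IntegerVector pad) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3], N = xdim[4];
  const int KD = kdim[0], KH = kdim[1], KW = kdim[2];
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int pd = pad[0], ph = pad[1], pw = pad[2];
  const int OD = (D + 2 * pd - KD) / sd + 1;
  const int OH = (H + 2 * ph - KH) / sh + 1;
  const int OW = (W + 2 * pw - KW) / sw + 1;
  const int Cout = Wm.nrow();
  const int K = C * KD * KH * KW;
  const int P = OD * OH * OW;
  const size_t sampIn = (size_t)C * D * H * W;
  const size_t sampOut = (size_t)Cout * P;

  NumericVector dx((R_xlen_t)(sampIn * N));
  dx.attr("dim") = xdim;
  NumericMatrix dW(Cout, K);
  NumericVector db(Cout);
  arma::mat Wa(Wm.begin(), Cout, K, false, true);
  arma::mat dWa(dW.begin(), Cout, K, false, true);
  arma::colvec dba(db.begin(), Cout, false, true);
  arma::mat col(K, P), dcol(K, P);
  for (int n = 0; n < N; ++n) {
    im2col3d(x.begin() + n * sampIn, C, D, H, W, KD, KH, KW,
             sd, sh, sw, pd, ph, pw, OD, OH, OW, col);
    arma::mat doutm(const_cast<double*>(dout.begin()) + n * sampOut,
                    Cout, P, false, true);
    dWa += doutm * col.t();
    dba += arma::sum(doutm, 1);
    dcol = Wa.t() * doutm;
    col2im3d(dcol, dx.begin() + n * sampIn, C, D, H, W, KD, KH, KW,
             sd, sh, sw, pd, ph, pw, OD, OH, OW);
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// Max pooling with stride equal to kernel and no padding (floor division of
// each spatial dimension); argmax indices (1-based, into x) kept for backward.
// [[Rcpp::export(name = ".maxpool3d_fwd")]]
List maxpool3d_fwd(NumericVector x, IntegerVector xdim, IntegerVector kdim) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3], N = xdim[4];
  const int KD = kdim[0], KH = kdim[1], KW = kdim[2];
  const int OD = D / KD, OH = H / KH, OW = W / KW;
  if (OD < 1 || OH < 1 || OW < 1) stop("pooling output has empty dimension");
  const size_t sampIn = (size_t)C * D * H * W;
  const size_t sampOut = (size_t)C * OD * OH * OW;

  NumericVector out((R_xlen_t)(sampOut * N));
  out.attr("dim") = IntegerVector::create(C, OD, OH, OW, N);
  IntegerVector arg((R_xlen_t)(sampOut * N));
  const double* xp = x.begin();
  double* op = out.begin();
  int* ap = arg.begin();
  for (int n = 0; n < N; ++n) {
    const size_t xoff = n * sampIn;
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh)
        for (int od = 0; od < OD; ++od)
          for (int c = 0; c < C; ++c) {
            double best = R_NegInf;
            size_t besti = 0;
            for (int zw = 0; zw < KW; ++zw)
              for (int zh = 0; zh < KH; ++zh)
                for (int zd = 0; zd < KD; ++zd) {
                  const int id = od * KD + zd;
                  const int ih = oh * KH + zh;
                  const int iw = ow * KW + zw;
                  const size_t idx =
                      xoff + c +
                      (size_t)C * (id + (size_t)D * (ih + (size_t)H * iw));
                  if (xp[idx] > best) { best = xp[idx]; besti = idx; }
                }
            const size_t o =
                n * sampOut + c +
                (size_t)C * (od + (size_t)OD * (oh + (size_t)OH * ow));
            op[o] = best;
            ap[o] = (int)(besti + 1);
          }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool3d_bwd")]]
NumericVector maxpool3d_bwd(NumericVector dout, IntegerVector argmax,
                            IntegerVector xdim) {
  R_xlen_t len = 1;
  for (int i = 0; i < xdim.size(); ++i) len *= xdim[i];
  NumericVector dx(len);
  dx.attr("dim") = xdim;
  double* dxp = dx.begin();
  const double* dop = dout.begin();
  const int* ap = argmax.begin();
  for (R_xlen_t i = 0; i < dout.size(); ++i) dxp[ap[i] - 1] += dop[i];
  return dx;
}
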