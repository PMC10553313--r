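// Dense numeric kernels for the attention cascade: im2col convolution with
// ReLU + 2x2 max pooling (forward/backward), the soft-boxcar crop-and-zoom
// with analytic gradients w.r.t. both the source image and the box
// parameters, bilinear rotation for augmentation, and a vectorised
// fused-weight accuracy sweep used by the PSO grid oracle.
//
// Array convention: R arrays dim c(H, W, C); element (y, x, channel),
// x rightward along columns, y downward along rows, 0-based pixel centres.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double sigm(double z) {
  // numerically safe logistic
  if (z >= 0.0) {
    double e = std::exp(-z);
    return 1.0 / (1.0 + e);
  }
  double e = std::exp(z);
  return e / (1.0 + e);
}

static inline double dsigm(double z) {
  double s = sigm(z);
  return s * (1.0 - s);
}

// im2col for a 3x3 kernel, zero padding 1, stride 1.
// Output: (H*W) x (9*Cin); row p = x*H + y; column ch*9 + (dx+1)*3 + (dy+1).
static arma::mat im2col3(const arma::cube& X) {
  const int H = X.n_rows, W = X.n_cols, Cin = X.n_slices;
  arma::mat cols(H * W, 9 * Cin, arma::fill::zeros);
  for (int ch = 0; ch < Cin; ++ch) {
    const arma::mat& S = X.slice(ch);
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        const int col = ch * 9 + (dx + 1) * 3 + (dy + 1);
        for (int x = 0; x < W; ++x) {
          const int xs = x + dx;
          if (xs < 0 || xs >= W) continue;
          const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
          double* dst = cols.colptr(col) + x * H;
          const double* src = S.colptr(xs);
          for (int y = y0; y < y1; ++y) dst[y] = src[y + dy];
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
List cpp_conv_pool_forward(const arma::cube& X, const arma::mat& W,
                           const arma::vec& b) {
  const int H = X.n_rows, Wd = X.n_cols;
  const int Cout = W.n_cols;
  if ((int)W.n_rows != 9 * (int)X.n_slices)
    stop("weight matrix rows must equal 9 * input channels");
  if (H % 2 != 0 || Wd % 2 != 0)
    stop("spatial size must be even for 2x2 pooling");
  arma::mat cols = im2col3(X);
  arma::mat Z = cols * W;
  Z.each_row() += b.t();
  Z.transform([](double v) { return v > 0.0 ? v : 0.0; });  // ReLU
  const int Ho = H / 2, Wo = Wd / 2;
  arma::cube out(Ho, Wo, Cout);
  arma::umat amax(Ho * Wo, Cout);
  for (int c = 0; c < Cout; ++c) {
    // Z column c is the column-major (H x W) activation map
    const double* A = Z.colptr(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int y = 2 * i, x = 2 * j;
        int best = y + x * H;
        double bv = A[best];
        const int cand[3] = { (y + 1) + x * H, y + (x + 1) * H,
                              (y + 1) + (x + 1) * H };
        for (int k = 0; k < 3; ++k)
          if (A[cand[k]] > bv) { bv = A[cand[k]]; best = cand[k]; }
        out(i, j, c) = bv;
        amax(j * Ho + i, c) = best;
      }
    }
  }
  return List::create(_["out"] = out, _["act"] = Z, _["cols"] = cols,
                      _["argmax"] = amax);
}

// [[Rcpp::export]]
List cpp_conv_pool_backward(const arma::cube& dOut, const arma::mat& act,
                            const arma::mat& cols, const arma::umat& amax,
                            const arma::mat& W, int H, int Wd,
                            bool want_dx) {
  const int Ho = dOut.n_rows, Wo = dOut.n_cols, Cout = dOut.n_slices;
  const int Cin = W.n_rows / 9;
  arma::mat dZ(H * Wd, Cout, arma::fill::zeros);
  for (int c = 0; c < Cout; ++c) {
    const double* A = act.colptr(c);
    double* dz = dZ.colptr(c);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const arma::uword idx = amax(j * Ho + i, c);
        if (A[idx] > 0.0) dz[idx] += dOut(i, j, c);  // ReLU gate
      }
  }
  arma::mat dW = cols.t() * dZ;
  arma::vec db = arma::sum(dZ, 0).t();
  arma::cube dX;
  if (want_dx) {
    dX.zeros(H, Wd, Cin);
    arma::mat dcols = dZ * W.t();
    for (int ch = 0; ch < Cin; ++ch) {
      arma::mat& D = dX.slice(ch);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy) {
          const int col = ch * 9 + (dx + 1) * 3 + (dy + 1);
          for (int x = 0; x < Wd; ++x) {
            const int xs = x + dx;
            if (xs < 0 || xs >= Wd) continue;
            const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
            const double* src = dcols.colptr(col) + x * H;
            double* dst = D.colptr(xs);
            for (int y = y0; y < y1; ++y) dst[y + dy] += src[y];
          }
        }
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dX);
}

// Soft mask factors along one axis. Pixel-area convention: pixel x
// occupies [x - 0.5, x + 0.5], so the step edges sit half a pixel outside
// the box corners; a box whose corners land exactly on pixel centres then
// fully includes those pixels in the high-steepness limit.
static arma::vec mask_axis(int n, double a, double b, double k) {
  arma::vec m(n);
  for (int x = 0; x < n; ++x)
    m(x) = sigm(k * (x - a + 0.5)) - sigm(k * (x - b - 0.5));
  return m;
}

// [[Rcpp::export]]
arma::mat cpp_attention_mask(int H, int W, double tx, double ty, double tl,
                             double k) {
  arma::vec mx = mask_axis(W, tx - tl, tx + tl, k);
  arma::vec my = mask_axis(H, ty - tl, ty + tl, k);
  return my * mx.t();
}

// [[Rcpp::export]]
arma::cube cpp_crop_zoom(const arma::cube& X, double tx, double ty, double tl,
                         double k, int S) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  arma::vec mx = mask_axis(W, tx - tl, tx + tl, k);
  arma::vec my = mask_axis(H, ty - tl, ty + tl, k);
  arma::cube out(S, S, C);
  const double step = (S > 1) ? 2.0 * tl / (S - 1) : 0.0;
  for (int j = 0; j < S; ++j) {
    double u = (S > 1) ? (tx - tl + j * step) : tx;
    u = std::min(std::max(u, 0.0), (double)(W - 1));
    const int x0 = std::min((int)std::floor(u), W - 2 >= 0 ? W - 2 : 0);
    const int x1 = std::min(x0 + 1, W - 1);
    const double wx = u - x0;
    for (int i = 0; i < S; ++i) {
      double v = (S > 1) ? (ty - tl + i * step) : ty;
      v = std::min(std::max(v, 0.0), (double)(H - 1));
      const int y0 = std::min((int)std::floor(v), H - 2 >= 0 ? H - 2 : 0);
      const int y1 = std::min(y0 + 1, H - 1);
      const double wy = v - y0;
      for (int c = 0; c < C; ++c) {
        const double V00 = X(y0, x0, c) * mx(x0) * my(y0);
        const double V01 = X(y0, x1, c) * mx(x1) * my(y0);
        const double V10 = X(y1, x0, c) * mx(x0) * my(y1);
        const double V11 = X(y1, x1, c) * mx(x1) * my(y1);
        out(i, j, c) = (1 - wy) * ((1 - wx) * V00 + wx * V01) +
                       wy * ((1 - wx) * V10 + wx * V11);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_crop_zoom_backward(const arma::cube& X, double tx, double ty,
                            double tl, double k, int S,
                            const arma::cube& dOut) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const double a = tx - tl, b = tx + tl, cc = ty - tl, d = ty + tl;
  arma::vec mx(W), my(H), dmx_tx(W), dmx_tl(W), dmy_ty(H), dmy_tl(H);
  for (int x = 0; x < W; ++x) {
    const double sa = dsigm(k * (x - a + 0.5)) * k;
    const double sb = dsigm(k * (x - b - 0.5)) * k;
    mx(x) = sigm(k * (x - a + 0.5)) - sigm(k * (x - b - 0.5));
    dmx_tx(x) = -sa + sb;   // both corners shift with tx
    dmx_tl(x) = sa + sb;    // a shrinks, b grows with tl
  }
  for (int y = 0; y < H; ++y) {
    const double sc = dsigm(k * (y - cc + 0.5)) * k;
    const double sd = dsigm(k * (y - d - 0.5)) * k;
    my(y) = sigm(k * (y - cc + 0.5)) - sigm(k * (y - d - 0.5));
    dmy_ty(y) = -sc + sd;
    dmy_tl(y) = sc + sd;
  }
  arma::cube dX(H, W, C, arma::fill::zeros);
  double dtx = 0.0, dty = 0.0, dtl = 0.0;
  const double step = (S > 1) ? 2.0 * tl / (S - 1) : 0.0;
  for (int j = 0; j < S; ++j) {
    double u = (S > 1) ? (a + j * step) : tx;
    const bool uin = (u > 0.0 && u < W - 1);  // clamped => no grid gradient
    u = std::min(std::max(u, 0.0), (double)(W - 1));
    const int x0 = std::min((int)std::floor(u), W - 2 >= 0 ? W - 2 : 0);
    const int x1 = std::min(x0 + 1, W - 1);
    const double wx = u - x0;
    const double du_dtl = (S > 1) ? (-1.0 + 2.0 * j / (S - 1)) : 0.0;
    for (int i = 0; i < S; ++i) {
      double v = (S > 1) ? (cc + i * step) : ty;
      const bool vin = (v > 0.0 && v < H - 1);
      v = std::min(std::max(v, 0.0), (double)(H - 1));
      const int y0 = std::min((int)std::floor(v), H - 2 >= 0 ? H - 2 : 0);
      const int y1 = std::min(y0 + 1, H - 1);
      const double wy = v - y0;
      const double dv_dtl = (S > 1) ? (-1.0 + 2.0 * i / (S - 1)) : 0.0;
      for (int c = 0; c < C; ++c) {
        const double g = dOut(i, j, c);
        if (g == 0.0) continue;
        const double X00 = X(y0, x0, c), X01 = X(y0, x1, c);
        const double X10 = X(y1, x0, c), X11 = X(y1, x1, c);
        const double V00 = X00 * mx(x0) * my(y0), V01 = X01 * mx(x1) * my(y0);
        const double V10 = X10 * mx(x0) * my(y1), V11 = X11 * mx(x1) * my(y1);
        const double w00 = (1 - wy) * (1 - wx), w01 = (1 - wy) * wx;
        const double w10 = wy * (1 - wx), w11 = wy * wx;
        // grid-motion term
        const double dO_du = (1 - wy) * (V01 - V00) + wy * (V11 - V10);
        const double dO_dv = (1 - wx) * (V10 - V00) + wx * (V11 - V01);
        // mask-motion term: d(mx*my)/dtheta at each corner
        const double mtx = w00 * X00 * dmx_tx(x0) * my(y0) +
                           w01 * X01 * dmx_tx(x1) * my(y0) +
                           w10 * X10 * dmx_tx(x0) * my(y1) +
                           w11 * X11 * dmx_tx(x1) * my(y1);
        const double mty = w00 * X00 * mx(x0) * dmy_ty(y0) +
                           w01 * X01 * mx(x1) * dmy_ty(y0) +
                           w10 * X10 * mx(x0) * dmy_ty(y1) +
                           w11 * X11 * mx(x1) * dmy_ty(y1);
        const double mtl = w00 * X00 * (dmx_tl(x0) * my(y0) + mx(x0) * dmy_tl(y0)) +
                           w01 * X01 * (dmx_tl(x1) * my(y0) + mx(x1) * dmy_tl(y0)) +
                           w10 * X10 * (dmx_tl(x0) * my(y1) + mx(x0) * dmy_tl(y1)) +
                           w11 * X11 * (dmx_tl(x1) * my(y1) + mx(x1) * dmy_tl(y1));
        dtx += g * ((uin ? dO_du : 0.0) + mtx);
        dty += g * ((vin ? dO_dv : 0.0) + mty);
        dtl += g * ((uin ? dO_du * du_dtl : 0.0) +
                    (vin ? dO_dv * dv_dtl : 0.0) + mtl);
        dX(y0, x0, c) += g * w00 * mx(x0) * my(y0);
        dX(y0, x1, c) += g * w01 * mx(x1) * my(y0);
        dX(y1, x0, c) += g * w10 * mx(x0) * my(y1);
        dX(y1, x1, c) += g * w11 * mx(x1) * my(y1);
      }
    }
  }
  arma::vec dbox = { dtx, dty, dtl };
  return List::create(_["dbox"] = dbox, _["dX"] = dX);
}

// [[Rcpp::export]]
arma::cube cpp_rotate_bilinear(const arma::cube& X, double angle_deg,
                               double fill) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const double th = angle_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double cx = (W - 1) / 2.0, cy = (H - 1) / 2.0;
  arma::cube out(H, W, C);
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      // inverse rotation about the image centre
      const double dx = x - cx, dy = y - cy;
      const double u = cx + ct * dx + st * dy;
      const double v = cy - st * dx + ct * dy;
      if (u < 0 || u > W - 1 || v < 0 || v > H - 1) {
        for (int c = 0; c < C; ++c) out(y, x, c) = fill;
        continue;
      }
      const int x0 = std::min((int)std::floor(u), W - 2 >= 0 ? W - 2 : 0);
      const int y0 = std::min((int)std::floor(v), H - 2 >= 0 ? H - 2 : 0);
      const int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
      const double wx = u - x0, wy = v - y0;
      for (int c = 0; c < C; ++c)
        out(y, x, c) = (1 - wy) * ((1 - wx) * X(y0, x0, c) + wx * X(y0, x1, c)) +
                       wy * ((1 - wx) * X(y1, x0, c) + wx * X(y1, x1, c));
    }
  }
  return out;
}

// Accuracy of the fused classifier at each candidate weight vector.
// P: n x C x K cube of per-head class probabilities; labels 0-based;
// Wgrid: G x K, rows are (already normalised) weight vectors.
// [[Rcpp::export]]
arma::vec cpp_fuse_grid_accuracy(const arma::cube& P,
                                 const arma::ivec& labels,
                                 const arma::mat& Wgrid) {
  const int n = P.n_rows, C = P.n_cols, K = P.n_slices, G = Wgrid.n_rows;
  arma::vec acc(G, arma::fill::zeros);
  for (int g = 0; g < G; ++g) {
    int hits = 0;
    for (int s = 0; s < n; ++s) {
      int best = 0;
      double bv = -1.0;
      for (int c = 0; c < C; ++c) {
        double f = 0.0;
        for (int k = 0; k < K; ++k) f += Wgrid(g, k) * P(s, c, k);
        if (f > bv + 1e-15) { bv = f; best = c; }  // lowest-index tie-break
      }
      if (best == (int)labels(s)) ++hits;
    }
    acc(g) = (double)hits / n;
  }
  return acc;
}
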