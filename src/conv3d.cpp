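// Dense 3-D convolution primitives for the (2+1)D U-Net.
//
// Array layout is channels-last, column-major: an activation tensor has
// dim (D, H, W, C) so linear index = d + D*(h + H*(w + W*c)).
// Convolution weights have dim (kd, kh, kw, Cin, Cout); transpose-conv
// weights use the same layout. All convolutions are stride 1 with "same"
// zero padding (odd kernels only) except the 2x2x2 stride-2 transpose
// convolution, where kernel == stride so output voxels receive exactly
// one contribution.

#include <Rcpp.h>
using namespace Rcpp;

static inline int idx4(int d, int h, int w, int c, int D, int H, int W) {
  return d + D * (h + H * (w + W * c));
}

// [[Rcpp::export]]
NumericVector conv3d_fwd(NumericVector x, IntegerVector xd,
                         NumericVector wt, IntegerVector wd,
                         NumericVector bias) {
  const int D = xd[0], H = xd[1], W = xd[2], Cin = xd[3];
  const int kd = wd[0], kh = wd[1], kw = wd[2], Cout = wd[4];
  const int pd = (kd - 1) / 2, ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericVector out((R_xlen_t)D * H * W * Cout);
  double *po = out.begin();
  const double *px = x.begin(), *pw_ = wt.begin(), *pb = bias.begin();

  for (int co = 0; co < Cout; ++co) {
    double b = pb[co];
    double *o = po + (R_xlen_t)D * H * W * co;
    for (R_xlen_t i = 0; i < (R_xlen_t)D * H * W; ++i) o[i] = b;
  }
  for (int co = 0; co < Cout; ++co) {
    double *obase = po + (R_xlen_t)D * H * W * co;
    for (int ci = 0; ci < Cin; ++ci) {
      const double *xbase = px + (R_xlen_t)D * H * W * ci;
      for (int c = 0; c < kw; ++c) {
        int dw = c - pw;
        int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
        for (int b_ = 0; b_ < kh; ++b_) {
          int dh = b_ - ph;
          int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          for (int a = 0; a < kd; ++a) {
            int dd = a - pd;
            int d0 = std::max(0, -dd), d1 = std::min(D, D - dd);
            double wv = pw_[a + kd * (b_ + kh * (c + kw * (ci + (R_xlen_t)Cin * co)))];
            if (wv == 0.0) continue;
            for (int w = w0; w < w1; ++w) {
              for (int h = h0; h < h1; ++h) {
                double *o = obase + D * (h + (R_xlen_t)H * w);
                const double *xi = xbase + (R_xlen_t)(d0 + dd) +
                                   D * ((h + dh) + (R_xlen_t)H * (w + dw));
                for (int d = d0; d < d1; ++d)
                  o[d] += wv * xi[d - d0];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Gradients of conv3d_fwd. Returns list(gx, gw, gb) given upstream
// gradient gy with the same extents as the forward output.
// [[Rcpp::export]]
List conv3d_bwd(NumericVector x, IntegerVector xd,
                NumericVector wt, IntegerVector wd,
                NumericVector gy) {
  const int D = xd[0], H = xd[1], W = xd[2], Cin = xd[3];
  const int kd = wd[0], kh = wd[1], kw = wd[2], Cout = wd[4];
  const int pd = (kd - 1) / 2, ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericVector gx((R_xlen_t)D * H * W * Cin);
  NumericVector gw(wt.size());
  NumericVector gb(Cout);
  const double *px = x.begin(), *pw_ = wt.begin(), *pg = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin(), *pgb = gb.begin();

  for (int co = 0; co < Cout; ++co) {
    const double *g = pg + (R_xlen_t)D * H * W * co;
    double s = 0.0;
    for (R_xlen_t i = 0; i < (R_xlen_t)D * H * W; ++i) s += g[i];
    pgb[co] = s;
  }
  for (int co = 0; co < Cout; ++co) {
    const double *gbase = pg + (R_xlen_t)D * H * W * co;
    for (int ci = 0; ci < Cin; ++ci) {
      const double *xbase = px + (R_xlen_t)D * H * W * ci;
      double *gxbase = pgx + (R_xlen_t)D * H * W * ci;
      for (int c = 0; c < kw; ++c) {
        int dw = c - pw;
        int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
        for (int b_ = 0; b_ < kh; ++b_) {
          int dh = b_ - ph;
          int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          for (int a = 0; a < kd; ++a) {
            int dd = a - pd;
            int d0 = std::max(0, -dd), d1 = std::min(D, D - dd);
            R_xlen_t widx = a + kd * (b_ + kh * (c + kw * (ci + (R_xlen_t)Cin * co)));
            double wv = pw_[widx];
            double acc = 0.0;
            for (int w = w0; w < w1; ++w) {
              for (int h = h0; h < h1; ++h) {
                const double *g = gbase + D * (h + (R_xlen_t)H * w);
                const double *xi = xbase + (R_xlen_t)(d0 + dd) +
                                   D * ((h + dh) + (R_xlen_t)H * (w + dw));
                double *gxi = gxbase + (R_xlen_t)(d0 + dd) +
                              D * ((h + dh) + (R_xlen_t)H * (w + dw));
                for (int d = d0; d < d1; ++d) {
                  double gv = g[d];
                  acc += gv * xi[d - d0];
                  gxi[d - d0] += wv * gv;
                }
              }
            }
            pgw[widx] += acc;
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2x2 stride-2 transpose convolution (kernel == stride, no overlap).
// Weights dim (2,2,2,Cin,Cout); output extents are 2x the input's.
// [[Rcpp::export]]
NumericVector tconv3d_fwd(NumericVector x, IntegerVector xd,
                          NumericVector wt, NumericVector bias) {
  const int D = xd[0], H = xd[1], W = xd[2], Cin = xd[3];
  const int Cout = bias.size();
  const int Do = 2 * D, Ho = 2 * H, Wo = 2 * W;
  NumericVector out((R_xlen_t)Do * Ho * Wo * Cout);
  const double *px = x.begin(), *pw = wt.begin(), *pb = bias.begin();
  double *po = out.begin();
  for (int co = 0; co < Cout; ++co) {
    for (int w = 0; w < Wo; ++w) {
      int wi = w >> 1, kc = w & 1;
      for (int h = 0; h < Ho; ++h) {
        int hi = h >> 1, kb = h & 1;
        for (int d = 0; d < Do; ++d) {
          int di = d >> 1, ka = d & 1;
          double s = pb[co];
          for (int ci = 0; ci < Cin; ++ci)
            s += pw[ka + 2 * (kb + 2 * (kc + 2 * (ci + (R_xlen_t)Cin * co)))] *
                 px[idx4(di, hi, wi, ci, D, H, W)];
          po[idx4(d, h, w, co, Do, Ho, Wo)] = s;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List tconv3d_bwd(NumericVector x, IntegerVector xd,
                 NumericVector wt, int Cout, NumericVector gy) {
  const int D = xd[0], H = xd[1], W = xd[2], Cin = xd[3];
  const int Do = 2 * D, Ho = 2 * H, Wo = 2 * W;
  NumericVector gx((R_xlen_t)D * H * W * Cin);
  NumericVector gw(wt.size());
  NumericVector gb(Cout);
  const double *px = x.begin(), *pw = wt.begin(), *pg = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin(), *pgb = gb.begin();
  for (int co = 0; co < Cout; ++co) {
    for (int w = 0; w < Wo; ++w) {
      int wi = w >> 1, kc = w & 1;
      for (int h = 0; h < Ho; ++h) {
        int hi = h >> 1, kb = h & 1;
        for (int d = 0; d < Do; ++d) {
          int di = d >> 1, ka = d & 1;
          double gv = pg[idx4(d, h, w, co, Do, Ho, Wo)];
          pgb[co] += gv;
          for (int ci = 0; ci < Cin; ++ci) {
            R_xlen_t widx = ka + 2 * (kb + 2 * (kc + 2 * (ci + (R_xlen_t)Cin * co)));
            pgw[widx] += gv * px[idx4(di, hi, wi, ci, D, H, W)];
            pgx[idx4(di, hi, wi, ci, D, H, W)] += gv * pw[widx];
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2x2 max pooling, stride 2. Returns list(y, argmax) where argmax holds
// 1-based linear indices into the input (per channel slab) for backward.
// Ties take the first (lowest-index) element, deterministically.
// [[Rcpp::export]]
List maxpool3d_fwd(NumericVector x, IntegerVector xd) {
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int Do = D / 2, Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)Do * Ho * Wo * C);
  IntegerVector arg((R_xlen_t)Do * Ho * Wo * C);
  const double *px = x.begin();
  double *po = out.begin();
  int *pa = arg.begin();
  for (int c = 0; c < C; ++c) {
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        for (int d = 0; d < Do; ++d) {
          double best = R_NegInf; R_xlen_t bi = -1;
          for (int kc = 0; kc < 2; ++kc)
            for (int kb = 0; kb < 2; ++kb)
              for (int ka = 0; ka < 2; ++ka) {
                R_xlen_t ii = idx4(2 * d + ka, 2 * h + kb, 2 * w + kc, c, D, H, W);
                if (px[ii] > best) { best = px[ii]; bi = ii; }
              }
          R_xlen_t oi = idx4(d, h, w, c, Do, Ho, Wo);
          po[oi] = best;
          pa[oi] = (int)(bi + 1);
        }
      }
    }
  }
  return List::create(_["y"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bwd(IntegerVector argmax, NumericVector gy,
                            R_xlen_t inputLength) {
  NumericVector gx(inputLength);
  double *pgx = gx.begin();
  const double *pg = gy.begin();
  const int *pa = argmax.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i)
    pgx[pa[i] - 1] += pg[i];
  return gx;
}
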