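#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Tensors are R arrays with dim (B, H, W, C), column-major:
//   index(b,i,j,c) = b + B*(i + H*(j + W*c)).
// Batch is innermost, so inner loops over b touch contiguous memory.
// Padding amounts (pt = top rows, pl = left columns) and output sizes are
// precomputed in R ("same" convention).

static inline R_xlen_t idx4(R_xlen_t b, R_xlen_t i, R_xlen_t j, R_xlen_t c,
                            R_xlen_t B, R_xlen_t H, R_xlen_t W) {
  return b + B * (i + H * (j + W * c));
}

// 4-way unrolled sum; serial FP chains are latency-bound otherwise.
static inline double vsum(const double* p, R_xlen_t n) {
  double a0 = 0.0, a1 = 0.0, a2 = 0.0, a3 = 0.0;
  R_xlen_t t = 0;
  for (; t + 3 < n; t += 4) {
    a0 += p[t];
    a1 += p[t + 1];
    a2 += p[t + 2];
    a3 += p[t + 3];
  }
  for (; t < n; ++t) a0 += p[t];
  return a0 + a1 + a2 + a3;
}

static inline double vdot(const double* p, const double* q, R_xlen_t n) {
  double a0 = 0.0, a1 = 0.0, a2 = 0.0, a3 = 0.0;
  R_xlen_t t = 0;
  for (; t + 3 < n; t += 4) {
    a0 += p[t] * q[t];
    a1 += p[t + 1] * q[t + 1];
    a2 += p[t + 2] * q[t + 2];
    a3 += p[t + 3] * q[t + 3];
  }
  for (; t < n; ++t) a0 += p[t] * q[t];
  return a0 + a1 + a2 + a3;
}

// ---------------------------------------------------------------- im2col ----

// Column matrix for a dense convolution: rows ordered (b, io, jo) with b
// fastest, columns ordered (di, dj, ci), matching matrix(w, k*k*ci, co) so
// that y = col %*% wmat.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, IntegerVector dims, int k,
                         int stride, int pt, int pl, int ho, int wo) {
  const R_xlen_t B = dims[0], H = dims[1], W = dims[2], C = dims[3];
  NumericMatrix col((R_xlen_t)B * ho * wo, (R_xlen_t)k * k * C);
  double* cp = col.begin();
  const double* xp = x.begin();
  const R_xlen_t nrow = (R_xlen_t)B * ho * wo;
  for (R_xlen_t c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const R_xlen_t ccol = di + (R_xlen_t)k * (dj + (R_xlen_t)k * c);
        double* colc = cp + ccol * nrow;
        for (int jo = 0; jo < wo; ++jo) {
          const int jj = jo * stride - pl + dj;
          for (int io = 0; io < ho; ++io) {
            const int ii = io * stride - pt + di;
            double* dst = colc + (R_xlen_t)B * (io + (R_xlen_t)ho * jo);
            if (ii < 0 || ii >= H || jj < 0 || jj >= W) {
              for (R_xlen_t b = 0; b < B; ++b) dst[b] = 0.0;
            } else {
              const double* src = xp + idx4(0, ii, jj, c, B, H, W);
              for (R_xlen_t b = 0; b < B; ++b) dst[b] = src[b];
            }
          }
        }
      }
    }
  }
  return col;
}

// Scatter-accumulate a column matrix back to input space (conv backward wrt x).
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix col, IntegerVector dims, int k,
                         int stride, int pt, int pl, int ho, int wo) {
  const R_xlen_t B = dims[0], H = dims[1], W = dims[2], C = dims[3];
  NumericVector x((R_xlen_t)B * H * W * C);
  double* xp = x.begin();
  const double* cp = col.begin();
  const R_xlen_t nrow = (R_xlen_t)B * ho * wo;
  for (R_xlen_t c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const R_xlen_t ccol = di + (R_xlen_t)k * (dj + (R_xlen_t)k * c);
        const double* colc = cp + ccol * nrow;
        for (int jo = 0; jo < wo; ++jo) {
          const int jj = jo * stride - pl + dj;
          if (jj < 0 || jj >= W) continue;
          for (int io = 0; io < ho; ++io) {
            const int ii = io * stride - pt + di;
            if (ii < 0 || ii >= H) continue;
            const double* src = colc + (R_xlen_t)B * (io + (R_xlen_t)ho * jo);
            double* dst = xp + idx4(0, ii, jj, c, B, H, W);
            for (R_xlen_t b = 0; b < B; ++b) dst[b] += src[b];
          }
        }
      }
    }
  }
  x.attr("dim") = dims;
  return x;
}

// ------------------------------------------------------- depthwise conv ----

// Output-stationary: each output position accumulates its k*k window in a
// per-batch register block, so the tensors are traversed once.
// w has dim (k, k, C).
// [[Rcpp::export]]
NumericVector cpp_dwconv_fw(NumericVector x, IntegerVector dims,
                            NumericVector w, int k, int stride, int pt,
                            int pl, int ho, int wo) {
  const R_xlen_t B = dims[0], H = dims[1], W = dims[2], C = dims[3];
  NumericVector y((R_xlen_t)B * ho * wo * C);
  double* yp = y.begin();
  const double* xp = x.begin();
  const double* wp = w.begin();
  std::vector<double> acc(B);
  for (R_xlen_t c = 0; c < C; ++c) {
    const double* wc = wp + (R_xlen_t)k * k * c;
    for (int jo = 0; jo < wo; ++jo) {
      const int jbase = jo * stride - pl;
      const int djlo = jbase < 0 ? -jbase : 0;
      const int djhi = (W - 1 - jbase < k - 1) ? (int)(W - 1 - jbase) : k - 1;
      for (int io = 0; io < ho; ++io) {
        const int ibase = io * stride - pt;
        const int dilo = ibase < 0 ? -ibase : 0;
        const int dihi =
            (H - 1 - ibase < k - 1) ? (int)(H - 1 - ibase) : k - 1;
        for (R_xlen_t b = 0; b < B; ++b) acc[b] = 0.0;
        for (int dj = djlo; dj <= djhi; ++dj) {
          for (int di = dilo; di <= dihi; ++di) {
            const double wv = wc[di + k * dj];
            const double* src =
                xp + idx4(0, ibase + di, jbase + dj, c, B, H, W);
            for (R_xlen_t b = 0; b < B; ++b) acc[b] += wv * src[b];
          }
        }
        double* dst = yp + idx4(0, io, jo, c, B, ho, wo);
        for (R_xlen_t b = 0; b < B; ++b) dst[b] = acc[b];
      }
    }
  }
  y.attr("dim") = IntegerVector::create(B, ho, wo, C);
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv_bw(NumericVector x, IntegerVector dims, NumericVector w,
                   int k, NumericVector dy, int stride, int pt, int pl,
                   int ho, int wo) {
  const R_xlen_t B = dims[0], H = dims[1], W = dims[2], C = dims[3];
  NumericVector dx((R_xlen_t)B * H * W * C);
  NumericVector dw((R_xlen_t)k * k * C);
  double* dxp = dx.begin();
  double* dwp = dw.begin();
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* dyp = dy.begin();
  for (R_xlen_t c = 0; c < C; ++c) {
    const double* wc = wp + (R_xlen_t)k * k * c;
    double* dwc = dwp + (R_xlen_t)k * k * c;
    for (int jo = 0; jo < wo; ++jo) {
      const int jbase = jo * stride - pl;
      const int djlo = jbase < 0 ? -jbase : 0;
      const int djhi = (W - 1 - jbase < k - 1) ? (int)(W - 1 - jbase) : k - 1;
      for (int io = 0; io < ho; ++io) {
        const int ibase = io * stride - pt;
        const int dilo = ibase < 0 ? -ibase : 0;
        const int dihi =
            (H - 1 - ibase < k - 1) ? (int)(H - 1 - ibase) : k - 1;
        const double* g = dyp + idx4(0, io, jo, c, B, ho, wo);
        for (int dj = djlo; dj <= djhi; ++dj) {
          for (int di = dilo; di <= dihi; ++di) {
            const double wv = wc[di + k * dj];
            const R_xlen_t off = idx4(0, ibase + di, jbase + dj, c, B, H, W);
            const double* src = xp + off;
            double* dst = dxp + off;
            for (R_xlen_t b = 0; b < B; ++b) dst[b] += wv * g[b];
            dwc[di + k * dj] += vdot(g, src, B);
          }
        }
      }
    }
  }
  dx.attr("dim") = dims;
  dw.attr("dim") = IntegerVector::create(k, k, C);
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// --------------------------------------------------------- grouped conv ----

// Grouped convolution, output-stationary. w has dim (k, k, cin/g, cout);
// output channel co draws from input channels of its group. groups = 1 gives
// a dense convolution.
// [[Rcpp::export]]
NumericVector cpp_gconv_fw(NumericVector x, IntegerVector dims,
                           NumericVector w, int k, int cout, int groups,
                           int stride, int pt, int pl, int ho, int wo) {
  const R_xlen_t B = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const R_xlen_t cg_in = C / groups, cg_out = cout / groups;
  NumericVector y((R_xlen_t)B * ho * wo * cout);
  double* yp = y.begin();
  const double* xp = x.begin();
  const double* wp = w.begin();
  std::vector<double> acc(B);
  for (R_xlen_t co = 0; co < cout; ++co) {
    const R_xlen_t grp = co / cg_out;
    const double* wco = wp + (R_xlen_t)k * k * cg_in * co;
    for (int jo = 0; jo < wo; ++jo) {
      const int jbase = jo * stride - pl;
      const int djlo = jbase < 0 ? -jbase : 0;
      const int djhi = (W - 1 - jbase < k - 1) ? (int)(W - 1 - jbase) : k - 1;
      for (int io = 0; io < ho; ++io) {
        const int ibase = io * stride - pt;
        const int dilo = ibase < 0 ? -ibase : 0;
        const int dihi =
            (H - 1 - ibase < k - 1) ? (int)(H - 1 - ibase) : k - 1;
        for (R_xlen_t b = 0; b < B; ++b) acc[b] = 0.0;
        for (R_xlen_t cl = 0; cl < cg_in; ++cl) {
          const R_xlen_t ci = grp * cg_in + cl;
          const double* wcl = wco + (R_xlen_t)k * k * cl;
          for (int dj = djlo; dj <= djhi; ++dj) {
            for (int di = dilo; di <= dihi; ++di) {
              const double wv = wcl[di + k * dj];
              const double* src =
                  xp + idx4(0, ibase + di, jbase + dj, ci, B, H, W);
              for (R_xlen_t b = 0; b < B; ++b) acc[b] += wv * src[b];
            }
          }
        }
        double* dst = yp + idx4(0, io, jo, co, B, ho, wo);
        for (R_xlen_t b = 0; b < B; ++b) dst[b] = acc[b];
      }
    }
  }
  y.attr("dim") = IntegerVector::create(B, ho, wo, cout);
  return y;
}

// [[Rcpp::export]]
List cpp_gconv_bw(NumericVector x, IntegerVector dims, NumericVector w, int k,
                  int cout, int groups, NumericVector dy, int stride, int pt,
                  int pl, int ho, int wo) {
  const R_xlen_t B = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const R_xlen_t cg_in = C / groups, cg_out = cout / groups;
  NumericVector dx((R_xlen_t)B * H * W * C);
  NumericVector dw((R_xlen_t)k * k * cg_in * cout);
  double* dxp = dx.begin();
  double* dwp = dw.begin();
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* dyp = dy.begin();
  for (R_xlen_t co = 0; co < cout; ++co) {
    const R_xlen_t grp = co / cg_out;
    const double* wco = wp + (R_xlen_t)k * k * cg_in * co;
    double* dwco = dwp + (R_xlen_t)k * k * cg_in * co;
    for (int jo = 0; jo < wo; ++jo) {
      const int jbase = jo * stride - pl;
      const int djlo = jbase < 0 ? -jbase : 0;
      const int djhi = (W - 1 - jbase < k - 1) ? (int)(W - 1 - jbase) : k - 1;
      for (int io = 0; io < ho; ++io) {
        const int ibase = io * stride - pt;
        const int dilo = ibase < 0 ? -ibase : 0;
        const int dihi =
            (H - 1 - ibase < k - 1) ? (int)(H - 1 - ibase) : k - 1;
        const double* g = dyp + idx4(0, io, jo, co, B, ho, wo);
        for (R_xlen_t cl = 0; cl < cg_in; ++cl) {
          const R_xlen_t ci = grp * cg_in + cl;
          const double* wcl = wco + (R_xlen_t)k * k * cl;
          double* dwcl = dwco + (R_xlen_t)k * k * cl;
          for (int dj = djlo; dj <= djhi; ++dj) {
            for (int di = dilo; di <= dihi; ++di) {
              const double wv = wcl[di + k * dj];
              const R_xlen_t off =
                  idx4(0, ibase + di, jbase + dj, ci, B, H, W);
              const double* src = xp + off;
              double* dst = dxp + off;
              for (R_xlen_t b = 0; b < B; ++b) dst[b] += wv * g[b];
              dwcl[di + k * dj] += vdot(g, src, B);
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = dims;
  dw.attr("dim") = IntegerVector::create(k, k, cg_in, cout);
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// ------------------------------------------------------------ batch norm ----

// Training-mode forward: per-channel biased mean/variance over (B, H, W).
// act = 0: linear output; act = 1: fused ReLU6.
// [[Rcpp::export]]
List cpp_bn_fw(NumericVector x, IntegerVector dims, NumericVector gamma,
               NumericVector beta, double eps, int act) {
  const R_xlen_t B = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const R_xlen_t N = B * H * W;
  NumericVector y(x.size()), mean(C), invstd(C);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t c = 0; c < C; ++c) {
    const double* xc = xp + N * c;
    const double m = vsum(xc, N) / N;
    // var = E[x^2] - m^2 would lose precision; keep centered accumulation
    double v0 = 0.0, v1 = 0.0, v2 = 0.0, v3 = 0.0;
    R_xlen_t t = 0;
    for (; t + 3 < N; t += 4) {
      const double d0 = xc[t] - m, d1 = xc[t + 1] - m;
      const double d2 = xc[t + 2] - m, d3 = xc[t + 3] - m;
      v0 += d0 * d0;
      v1 += d1 * d1;
      v2 += d2 * d2;
      v3 += d3 * d3;
    }
    for (; t < N; ++t) {
      const double d0 = xc[t] - m;
      v0 += d0 * d0;
    }
    const double v = (v0 + v1 + v2 + v3) / N;
    const double is = 1.0 / std::sqrt(v + eps);
    const double g = gamma[c], bt = beta[c];
    double* yc = yp + N * c;
    if (act) {
      for (R_xlen_t t = 0; t < N; ++t) {
        double u = g * (xc[t] - m) * is + bt;
        yc[t] = u < 0.0 ? 0.0 : (u > 6.0 ? 6.0 : u);
      }
    } else {
      for (R_xlen_t t = 0; t < N; ++t) yc[t] = g * (xc[t] - m) * is + bt;
    }
    mean[c] = m;
    invstd[c] = is;
  }
  y.attr("dim") = dims;
  return List::create(_["y"] = y, _["mean"] = mean, _["invstd"] = invstd);
}

// Inference-mode forward with running statistics.
// [[Rcpp::export]]
NumericVector cpp_bn_fw_eval(NumericVector x, IntegerVector dims,
                             NumericVector gamma, NumericVector beta,
                             NumericVector rmean, NumericVector rvar,
                             double eps, int act) {
  const R_xlen_t B = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const R_xlen_t N = B * H * W;
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t c = 0; c < C; ++c) {
    const double is = 1.0 / std::sqrt(rvar[c] + eps);
    const double g = gamma[c], bt = beta[c], m = rmean[c];
    const double* xc = xp + N * c;
    double* yc = yp + N * c;
    if (act) {
      for (R_xlen_t t = 0; t < N; ++t) {
        double u = g * (xc[t] - m) * is + bt;
        yc[t] = u < 0.0 ? 0.0 : (u > 6.0 ? 6.0 : u);
      }
    } else {
      for (R_xlen_t t = 0; t < N; ++t) yc[t] = g * (xc[t] - m) * is + bt;
    }
  }
  y.attr("dim") = dims;
  return y;
}

// Backward through (optional ReLU6 followed by) batch norm. When act = 1,
// `yact` is the activated output used to mask the incoming gradient (values
// strictly inside (0, 6) pass through).
// [[Rcpp::export]]
List cpp_bn_bw(NumericVector x, IntegerVector dims, NumericVector dy,
               NumericVector yact, NumericVector gamma, NumericVector mean,
               NumericVector invstd, int act) {
  const R_xlen_t B = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const R_xlen_t N = B * H * W;
  NumericVector dx(x.size()), dgamma(C), dbeta(C);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  const double* yp = act ? yact.begin() : nullptr;
  double* dxp = dx.begin();
  for (R_xlen_t c = 0; c < C; ++c) {
    const double m = mean[c], is = invstd[c], g = gamma[c];
    const double* xc = xp + N * c;
    const double* dyc = dyp + N * c;
    const double* yc = act ? yp + N * c : nullptr;
    double s0 = 0.0, s1 = 0.0, x0 = 0.0, x1 = 0.0;
    R_xlen_t t = 0;
    for (; t + 1 < N; t += 2) {
      double g0 = dyc[t], g1 = dyc[t + 1];
      if (act) {
        if (yc[t] <= 0.0 || yc[t] >= 6.0) g0 = 0.0;
        if (yc[t + 1] <= 0.0 || yc[t + 1] >= 6.0) g1 = 0.0;
      }
      s0 += g0;
      s1 += g1;
      x0 += g0 * (xc[t] - m);
      x1 += g1 * (xc[t + 1] - m);
    }
    for (; t < N; ++t) {
      double gv = dyc[t];
      if (act && (yc[t] <= 0.0 || yc[t] >= 6.0)) gv = 0.0;
      s0 += gv;
      x0 += gv * (xc[t] - m);
    }
    const double sdy = s0 + s1;
    const double sdyx = (x0 + x1) * is;
    dgamma[c] = sdyx;
    dbeta[c] = sdy;
    const double a = g * is / N;
    double* dxc = dxp + N * c;
    for (R_xlen_t t = 0; t < N; ++t) {
      double gv = dyc[t];
      if (act && (yc[t] <= 0.0 || yc[t] >= 6.0)) gv = 0.0;
      const double xh = (xc[t] - m) * is;
      dxc[t] = a * (N * gv - sdy - xh * sdyx);
    }
  }
  dx.attr("dim") = dims;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// ----------------------------------------------------------------- relu6 ----

// [[Rcpp::export]]
NumericVector cpp_relu6_fw(NumericVector x) {
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t t = 0; t < n; ++t) {
    const double v = xp[t];
    yp[t] = v < 0.0 ? 0.0 : (v > 6.0 ? 6.0 : v);
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu6_bw(NumericVector x, NumericVector dy) {
  NumericVector dx(x.size());
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t t = 0; t < n; ++t) {
    const double v = xp[t];
    dxp[t] = (v > 0.0 && v < 6.0) ? dyp[t] : 0.0;
  }
  dx.attr("dim") = x.attr("dim");
  return dx;
}

// -------------------------------------------------- channel-group folding ----

// (B, H, W, cg*g) -> (B*g, H, W, cg); group index varies after batch.
// [[Rcpp::export]]
NumericVector cpp_fold_groups(NumericVector x, IntegerVector dims, int g) {
  const R_xlen_t B = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const R_xlen_t cg = C / g, BG = B * g, HW = H * W;
  NumericVector y(x.size());
  double* yp = y.begin();
  const double* xp = x.begin();
  for (R_xlen_t grp = 0; grp < g; ++grp) {
    for (R_xlen_t cl = 0; cl < cg; ++cl) {
      const double* src = xp + (R_xlen_t)B * HW * (grp * cg + cl);
      double* dstc = yp + BG * HW * cl + (R_xlen_t)B * grp;
      for (R_xlen_t s = 0; s < HW; ++s) {
        const double* sp = src + (R_xlen_t)B * s;
        double* dp = dstc + BG * s;
        for (R_xlen_t b = 0; b < B; ++b) dp[b] = sp[b];
      }
    }
  }
  y.attr("dim") = IntegerVector::create(BG, H, W, cg);
  return y;
}

// Inverse of cpp_fold_groups.
// [[Rcpp::export]]
NumericVector cpp_unfold_groups(NumericVector x, IntegerVector dims, int g) {
  const R_xlen_t BG = dims[0], H = dims[1], W = dims[2], cg = dims[3];
  const R_xlen_t B = BG / g, HW = H * W;
  NumericVector y(x.size());
  double* yp = y.begin();
  const double* xp = x.begin();
  for (R_xlen_t grp = 0; grp < g; ++grp) {
    for (R_xlen_t cl = 0; cl < cg; ++cl) {
      double* dst = yp + (R_xlen_t)B * HW * (grp * cg + cl);
      const double* srcc = xp + BG * HW * cl + (R_xlen_t)B * grp;
      for (R_xlen_t s = 0; s < HW; ++s) {
        double* dp = dst + (R_xlen_t)B * s;
        const double* sp = srcc + BG * s;
        for (R_xlen_t b = 0; b < B; ++b) dp[b] = sp[b];
      }
    }
  }
  y.attr("dim") = IntegerVector::create(B, H, W, cg * g);
  return y;
}

// ------------------------------------------------------- pooling kernels ----

// Mean over columns: (B,H,W,C) -> (B,H,1,C).
// [[Rcpp::export]]
NumericVector cpp_pool_h(NumericVector x, IntegerVector dims) {
  const R_xlen_t B = dims[0], H = dims[1], W = dims[2], C = dims[3];
  NumericVector y((R_xlen_t)B * H * C);
  double* yp = y.begin();
  const double* xp = x.begin();
  for (R_xlen_t c = 0; c < C; ++c) {
    double* yc = yp + (R_xlen_t)B * H * c;
    for (R_xlen_t j = 0; j < W; ++j) {
      const double* xc = xp + idx4(0, 0, j, c, B, H, W);
      for (R_xlen_t t = 0; t < B * H; ++t) yc[t] += xc[t];
    }
  }
  const double inv = 1.0 / W;
  for (R_xlen_t t = 0; t < (R_xlen_t)B * H * C; ++t) yp[t] *= inv;
  y.attr("dim") = IntegerVector::create(B, H, 1, C);
  return y;
}

// Mean over rows: (B,H,W,C) -> (B,1,W,C).
// [[Rcpp::export]]
NumericVector cpp_pool_v(NumericVector x, IntegerVector dims) {
  const R_xlen_t B = dims[0], H = dims[1], W = dims[2], C = dims[3];
  NumericVector y((R_xlen_t)B * W * C);
  double* yp = y.begin();
  const double* xp = x.begin();
  for (R_xlen_t c = 0; c < C; ++c) {
    for (R_xlen_t j = 0; j < W; ++j) {
      double* yc = yp + (R_xlen_t)B * (j + W * c);
      const double* xc = xp + idx4(0, 0, j, c, B, H, W);
      for (R_xlen_t i = 0; i < H; ++i) {
        const double* src = xc + B * i;
        for (R_xlen_t b = 0; b < B; ++b) yc[b] += src[b];
      }
    }
  }
  const double inv = 1.0 / H;
  for (R_xlen_t t = 0; t < (R_xlen_t)B * W * C; ++t) yp[t] *= inv;
  y.attr("dim") = IntegerVector::create(B, 1, W, C);
  return y;
}

// Mean over all spatial positions: (B,H,W,C) -> matrix (B,C).
// [[Rcpp::export]]
NumericMatrix cpp_pool_global(NumericVector x, IntegerVector dims) {
  const R_xlen_t B = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const R_xlen_t HW = H * W;
  NumericMatrix y(B, C);
  double* yp = y.begin();
  const double* xp = x.begin();
  for (R_xlen_t c = 0; c < C; ++c) {
    double* yc = yp + B * c;
    const double* xc = xp + B * HW * c;
    for (R_xlen_t s = 0; s < HW; ++s) {
      const double* src = xc + B * s;
      for (R_xlen_t b = 0; b < B; ++b) yc[b] += src[b];
    }
  }
  const double inv = 1.0 / HW;
  for (R_xlen_t t = 0; t < (R_xlen_t)B * C; ++t) yp[t] *= inv;
  return y;
}

// ------------------------------------------- EMA fused gating kernels ------

// y = x * sh * sw with sh (B,H,1,C), sw (B,1,W,C) broadcast over the missing
// axis.
// [[Rcpp::export]]
NumericVector cpp_dirgate_fw(NumericVector x, IntegerVector dims,
                             NumericVector sh, NumericVector sw) {
  const R_xlen_t B = dims[0], H = dims[1], W = dims[2], C = dims[3];
  NumericVector y(x.size());
  double* yp = y.begin();
  const double* xp = x.begin();
  const double* shp = sh.begin();
  const double* swp = sw.begin();
  for (R_xlen_t c = 0; c < C; ++c) {
    for (R_xlen_t j = 0; j < W; ++j) {
      const double* swc = swp + (R_xlen_t)B * (j + W * c);
      for (R_xlen_t i = 0; i < H; ++i) {
        const double* shc = shp + (R_xlen_t)B * (i + H * c);
        const R_xlen_t off = idx4(0, i, j, c, B, H, W);
        const double* src = xp + off;
        double* dst = yp + off;
        for (R_xlen_t b = 0; b < B; ++b)
          dst[b] = src[b] * shc[b] * swc[b];
      }
    }
  }
  y.attr("dim") = dims;
  return y;
}

// Backward of the directional gate: returns dx (contribution through x),
// dsh = sum_j dy*x*sw and dsw = sum_i dy*x*sh.
// [[Rcpp::export]]
List cpp_dirgate_bw(NumericVector x, IntegerVector dims, NumericVector sh,
                    NumericVector sw, NumericVector dy) {
  const R_xlen_t B = dims[0], H = dims[1], W = dims[2], C = dims[3];
  NumericVector dx(x.size());
  NumericVector dsh((R_xlen_t)B * H * C), dsw((R_xlen_t)B * W * C);
  double* dxp = dx.begin();
  double* dshp = dsh.begin();
  double* dswp = dsw.begin();
  const double* xp = x.begin();
  const double* shp = sh.begin();
  const double* swp = sw.begin();
  const double* dyp = dy.begin();
  for (R_xlen_t c = 0; c < C; ++c) {
    for (R_xlen_t j = 0; j < W; ++j) {
      const double* swc = swp + (R_xlen_t)B * (j + W * c);
      double* dswc = dswp + (R_xlen_t)B * (j + W * c);
      for (R_xlen_t i = 0; i < H; ++i) {
        const double* shc = shp + (R_xlen_t)B * (i + H * c);
        double* dshc = dshp + (R_xlen_t)B * (i + H * c);
        const R_xlen_t off = idx4(0, i, j, c, B, H, W);
        const double* src = xp + off;
        const double* g = dyp + off;
        double* dst = dxp + off;
        for (R_xlen_t b = 0; b < B; ++b) {
          const double gx = g[b] * src[b];
          dst[b] = g[b] * shc[b] * swc[b];
          dshc[b] += gx * swc[b];
          dswc[b] += gx * shc[b];
        }
      }
    }
  }
  dx.attr("dim") = dims;
  dsh.attr("dim") = IntegerVector::create(B, H, 1, C);
  dsw.attr("dim") = IntegerVector::create(B, 1, W, C);
  return List::create(_["dx"] = dx, _["dsh"] = dsh, _["dsw"] = dsw);
}

// y = x * wmap with wmap (B,H,W) broadcast over channels.
// [[Rcpp::export]]
NumericVector cpp_gate_fw(NumericVector x, IntegerVector dims,
                          NumericVector wmap) {
  const R_xlen_t B = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const R_xlen_t N = B * H * W;
  NumericVector y(x.size());
  double* yp = y.begin();
  const double* xp = x.begin();
  const double* wp = wmap.begin();
  for (R_xlen_t c = 0; c < C; ++c) {
    const double* xc = xp + N * c;
    double* yc = yp + N * c;
    for (R_xlen_t t = 0; t < N; ++t) yc[t] = xc[t] * wp[t];
  }
  y.attr("dim") = dims;
  return y;
}

// Backward of the channel-broadcast gate: dx = dy*w, dw = sum_c dy*x.
// [[Rcpp::export]]
List cpp_gate_bw(NumericVector x, IntegerVector dims, NumericVector wmap,
                 NumericVector dy) {
  const R_xlen_t B = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const R_xlen_t N = B * H * W;
  NumericVector dx(x.size());
  NumericVector dwm(N);
  double* dxp = dx.begin();
  double* dwp = dwm.begin();
  const double* xp = x.begin();
  const double* wp = wmap.begin();
  const double* dyp = dy.begin();
  for (R_xlen_t c = 0; c < C; ++c) {
    const double* xc = xp + N * c;
    const double* dyc = dyp + N * c;
    double* dxc = dxp + N * c;
    for (R_xlen_t t = 0; t < N; ++t) {
      dxc[t] = dyc[t] * wp[t];
      dwp[t] += dyc[t] * xc[t];
    }
  }
  dx.attr("dim") = dims;
  dwm.attr("dim") = IntegerVector::create(B, H, W);
  return List::create(_["dx"] = dx, _["dw"] = dwm);
}
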