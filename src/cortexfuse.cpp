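// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <queue>
using namespace Rcpp;

// 4-connected component labelling of a binary matrix (BFS flood fill).
// [[Rcpp::export]]
IntegerMatrix label_components_4(IntegerMatrix mask) {
  int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  int cur = 0;
  std::queue<std::pair<int, int>> q;
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      if (mask(i, j) > 0 && lab(i, j) == 0) {
        ++cur;
        lab(i, j) = cur;
        q.push({i, j});
        while (!q.empty()) {
          auto [r, c] = q.front();
          q.pop();
          const int dr[4] = {-1, 1, 0, 0};
          const int dc[4] = {0, 0, -1, 1};
          for (int k = 0; k < 4; ++k) {
            int rr = r + dr[k], cc = c + dc[k];
            if (rr >= 0 && rr < h && cc >= 0 && cc < w &&
                mask(rr, cc) > 0 && lab(rr, cc) == 0) {
              lab(rr, cc) = cur;
              q.push({rr, cc});
            }
          }
        }
      }
    }
  }
  return lab;
}

// patches-in-rows layout: M(ho*wo, kh*kw*cin), filled from a pre-padded
// sample so the inner loop over output rows is branch-free
static void im2col_rows(const arma::cube& xp, int kh, int kw, int stride,
                        int ho, int wo, arma::mat& M) {
  const int c = xp.n_slices;
  for (int ch = 0; ch < c; ++ch) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int col = ch * kh * kw + kj * kh + ki;
        double* dst = M.colptr(col);
        for (int oj = 0; oj < wo; ++oj) {
          const double* src = xp.slice_colptr(ch, oj * stride + kj) + ki;
          if (stride == 1) {
            std::copy(src, src + ho, dst);
            dst += ho;
          } else {
            for (int oi = 0; oi < ho; ++oi) dst[oi] = src[oi * stride];
            dst += ho;
          }
        }
      }
    }
  }
}

static void col2im_rows_add(arma::cube& xp, int kh, int kw, int stride,
                            int ho, int wo, const arma::mat& M) {
  const int c = xp.n_slices;
  for (int ch = 0; ch < c; ++ch) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int col = ch * kh * kw + kj * kh + ki;
        const double* src = M.colptr(col);
        for (int oj = 0; oj < wo; ++oj) {
          double* dst = xp.slice_colptr(ch, oj * stride + kj) + ki;
          if (stride == 1) {
            for (int oi = 0; oi < ho; ++oi) dst[oi] += src[oi];
          } else {
            for (int oi = 0; oi < ho; ++oi) dst[oi * stride] += src[oi];
          }
          src += ho;
        }
      }
    }
  }
}

static arma::cube pad_sample(const double* x, int h, int w, int c, int pad) {
  arma::cube xp(h + 2 * pad, w + 2 * pad, c, arma::fill::zeros);
  for (int ch = 0; ch < c; ++ch)
    for (int j = 0; j < w; ++j)
      std::copy(x + (size_t)ch * h * w + (size_t)j * h,
                x + (size_t)ch * h * w + (size_t)j * h + h,
                xp.slice_colptr(ch, j + pad) + pad);
  return xp;
}

// x: (H, W, Cin, N), w: (kh, kw, Cin, Cout), b: length Cout
// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int h = xd[0], wi = xd[1], cin = xd[2], n = xd[3];
  int kh = wd[0], kw = wd[1], cout = wd[3];
  int ho = (h + 2 * pad - kh) / stride + 1;
  int wo = (wi + 2 * pad - kw) / stride + 1;
  arma::mat Wm(w.begin(), kh * kw * cin, cout, false); // (khkwcin, cout)
  arma::rowvec bv(b.begin(), cout, false);
  NumericVector y(ho * wo * cout * n);
  y.attr("dim") = IntegerVector::create(ho, wo, cout, n);
  size_t xs = (size_t)h * wi * cin, ys = (size_t)ho * wo * cout;
  arma::mat M(ho * wo, kh * kw * cin);
  for (int s = 0; s < n; ++s) {
    arma::cube xp = pad_sample(x.begin() + s * xs, h, wi, cin, pad);
    im2col_rows(xp, kh, kw, stride, ho, wo, M);
    arma::mat Y(y.begin() + s * ys, ho * wo, cout, false, true);
    Y = M * Wm;                           // (ho*wo, cout)
    Y.each_row() += bv;
  }
  return y;
}

// gradients wrt x, w, b given upstream grad gy
// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                int stride, int pad, bool need_gx = true) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  int h = xd[0], wi = xd[1], cin = xd[2], n = xd[3];
  int kh = wd[0], kw = wd[1], cout = wd[3];
  int ho = gd[0], wo = gd[1];
  arma::mat Wm(w.begin(), kh * kw * cin, cout, false);
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  arma::mat gW(kh * kw * cin, cout, arma::fill::zeros);
  arma::rowvec gb(cout, arma::fill::zeros);
  size_t xs = (size_t)h * wi * cin, ys = (size_t)ho * wo * cout;
  arma::mat M(ho * wo, kh * kw * cin);
  for (int s = 0; s < n; ++s) {
    arma::mat Gy(const_cast<double*>(gy.begin()) + s * ys, ho * wo, cout,
                 false);
    arma::cube xp = pad_sample(x.begin() + s * xs, h, wi, cin, pad);
    im2col_rows(xp, kh, kw, stride, ho, wo, M);
    gW += M.t() * Gy;
    gb += arma::sum(Gy, 0);
    if (need_gx) {
      arma::mat Gcol = Gy * Wm.t();       // (ho*wo, khkwcin)
      arma::cube gxp(h + 2 * pad, wi + 2 * pad, cin, arma::fill::zeros);
      col2im_rows_add(gxp, kh, kw, stride, ho, wo, Gcol);
      arma::cube gxc(gx.begin() + s * xs, h, wi, cin, false, true);
      gxc = gxp.tube(pad, pad, pad + h - 1, pad + wi - 1);
    }
  }
  NumericVector gwv(gW.begin(), gW.end());
  gwv.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gwv,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// y = a[ch] * x + b[ch] over an (H, W, C, N) array
// [[Rcpp::export]]
NumericVector bn_scale_shift(NumericVector x, NumericVector a,
                             NumericVector b) {
  IntegerVector d = x.attr("dim");
  size_t hw = (size_t)d[0] * d[1];
  int c = d[2], n = d[3];
  NumericVector y(x.size());
  y.attr("dim") = d;
  const double* xs = x.begin();
  double* ys = y.begin();
  for (int s = 0; s < n; ++s)
    for (int ch = 0; ch < c; ++ch) {
      double aa = a[ch], bb = b[ch];
      size_t off = ((size_t)s * c + ch) * hw;
      for (size_t i = 0; i < hw; ++i) ys[off + i] = aa * xs[off + i] + bb;
    }
  return y;
}

// per-channel sum of x * y over (H, W, C, N); y may be NULL for sum(x)
// [[Rcpp::export]]
NumericVector channel_dot(NumericVector x, Nullable<NumericVector> y) {
  IntegerVector d = x.attr("dim");
  size_t hw = (size_t)d[0] * d[1];
  int c = d[2], n = d[3];
  NumericVector out(c);
  const double* xs = x.begin();
  const double* ys = y.isNotNull() ? NumericVector(y).begin() : nullptr;
  for (int s = 0; s < n; ++s)
    for (int ch = 0; ch < c; ++ch) {
      size_t off = ((size_t)s * c + ch) * hw;
      double acc = 0;
      if (ys) for (size_t i = 0; i < hw; ++i)
        acc += xs[off + i] * ys[off + i];
      else for (size_t i = 0; i < hw; ++i) acc += xs[off + i];
      out[ch] += acc;
    }
  return out;
}

// leaky ReLU forward
// [[Rcpp::export]]
NumericVector lrelu_fwd(NumericVector x, double slope) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i)
    y[i] = x[i] > 0 ? x[i] : slope * x[i];
  return y;
}

// leaky ReLU backward: g * (x > 0 ? 1 : slope)
// [[Rcpp::export]]
NumericVector lrelu_bwd(NumericVector x, NumericVector g, double slope) {
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = x[i] > 0 ? g[i] : slope * g[i];
  return out;
}

// One SLIC assignment sweep: pixels -> nearest center in (lab, xy/S * m) space.
// lab: (npix, 3) features in image order (column-major h*w), centers:
// (k, 5) = (L, a, b, row, col). Returns 1-based assignment per pixel.
// [[Rcpp::export]]
IntegerVector slic_assign(NumericMatrix lab, int h, int w,
                          NumericMatrix centers, double S, double m) {
  int k = centers.nrow();
  IntegerVector out(h * w);
  NumericVector best(h * w, R_PosInf);
  double invS = m / S;
  for (int c = 0; c < k; ++c) {
    int r0 = std::max(0, (int)std::floor(centers(c, 3) - 2 * S));
    int r1 = std::min(h - 1, (int)std::ceil(centers(c, 3) + 2 * S));
    int c0 = std::max(0, (int)std::floor(centers(c, 4) - 2 * S));
    int c1 = std::min(w - 1, (int)std::ceil(centers(c, 4) + 2 * S));
    for (int cc = c0; cc <= c1; ++cc) {
      for (int rr = r0; rr <= r1; ++rr) {
        int idx = cc * h + rr;
        double dl = lab(idx, 0) - centers(c, 0);
        double da = lab(idx, 1) - centers(c, 1);
        double db = lab(idx, 2) - centers(c, 2);
        double dr = (rr - centers(c, 3)) * invS;
        double dc = (cc - centers(c, 4)) * invS;
        double d = dl * dl + da * da + db * db + dr * dr + dc * dc;
        if (d < best[idx]) {
          best[idx] = d;
          out[idx] = c + 1;
        }
      }
    }
  }
  return out;
}

// nearest-centroid assignment of feature rows to centroid rows (1-based)
// [[Rcpp::export]]
IntegerVector assign_nearest(NumericMatrix feats, NumericMatrix centroids) {
  int n = feats.nrow(), k = centroids.nrow(), d = feats.ncol();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bj = 1;
    for (int j = 0; j < k; ++j) {
      double s = 0;
      for (int c = 0; c < d; ++c) {
        double df = feats(i, c) - centroids(j, c);
        s += df * df;
        if (s >= best) break;
      }
      if (s < best) { best = s; bj = j + 1; }
    }
    out[i] = bj;
  }
  return out;
}
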