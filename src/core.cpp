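#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// 1-D convolution kernels for the residual shrinkage network.
// Layout: signals are (W, C, N) arrays (width fastest), weights (K, Cin, Cout).
// Zero padding `pad` on both sides; output width = floor((W + 2p - K)/s) + 1.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector conv1d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int W = xd[0], Cin = xd[1], N = xd[2];
  const int K = wd[0], Cout = wd[2];
  const int Wo = (W + 2 * pad - K) / stride + 1;
  NumericVector y(Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Wo, Cout, N);
  const double *__restrict px = x.begin(), *__restrict pw = w.begin(), *__restrict pb = b.begin();
  double *__restrict py = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      double *yo = py + (size_t)n * Wo * Cout + (size_t)co * Wo;
      for (int wo = 0; wo < Wo; ++wo) yo[wo] = pb[co];
      for (int ci = 0; ci < Cin; ++ci) {
        const double *xi = px + (size_t)n * W * Cin + (size_t)ci * W;
        const double *wk = pw + (size_t)co * K * Cin + (size_t)ci * K;
        for (int k = 0; k < K; ++k) {
          const double wv = wk[k];
          // wo range with in-bounds input index wi = wo*stride + k - pad
          int lo = 0, hi = Wo - 1;
          if (k - pad < 0) lo = (pad - k + stride - 1) / stride;
          if ((hi * stride + k - pad) >= W) hi = (W - 1 - k + pad) / stride;
          const double *__restrict xs = xi + (size_t)(lo * stride + k - pad);
          if (stride == 1) {
            for (int wo = lo; wo <= hi; ++wo) yo[wo] += wv * xs[wo - lo];
          } else {
            for (int wo = lo; wo <= hi; ++wo)
              yo[wo] += wv * xs[(size_t)(wo - lo) * stride];
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv1d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = gy.attr("dim");
  const int W = xd[0], Cin = xd[1], N = xd[2];
  const int K = wd[0], Cout = wd[2];
  const int Wo = yd[0];
  NumericVector gx(W * Cin * N), gw(K * Cin * Cout), gb(Cout);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  const double *__restrict px = x.begin(), *__restrict pw = w.begin(), *__restrict pg = gy.begin();
  double *__restrict pgx = gx.begin(), *__restrict pgw = gw.begin(), *__restrict pgb = gb.begin();
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      const double *gyo = pg + (size_t)n * Wo * Cout + (size_t)co * Wo;
      double s = 0.0;
      for (int wo = 0; wo < Wo; ++wo) s += gyo[wo];
      pgb[co] += s;
      for (int ci = 0; ci < Cin; ++ci) {
        const double *xi = px + (size_t)n * W * Cin + (size_t)ci * W;
        double *gxi = pgx + (size_t)n * W * Cin + (size_t)ci * W;
        const double *wk = pw + (size_t)co * K * Cin + (size_t)ci * K;
        double *gwk = pgw + (size_t)co * K * Cin + (size_t)ci * K;
        for (int k = 0; k < K; ++k) {
          const double wv = wk[k];
          double acc = 0.0;
          int lo = 0, hi = Wo - 1;
          if (k - pad < 0) lo = (pad - k + stride - 1) / stride;
          if ((hi * stride + k - pad) >= W) hi = (W - 1 - k + pad) / stride;
          const size_t base = (size_t)(lo * stride + k - pad);
          if (stride == 1) {
            const double *__restrict xs = xi + base;
            double *__restrict gxs = gxi + base;
            for (int wo = lo; wo <= hi; ++wo) {
              acc += gyo[wo] * xs[wo - lo];
              gxs[wo - lo] += gyo[wo] * wv;
            }
          } else {
            for (int wo = lo; wo <= hi; ++wo) {
              const size_t wi = base + (size_t)(wo - lo) * stride;
              acc += gyo[wo] * xi[wi];
              gxi[wi] += gyo[wo] * wv;
            }
          }
          gwk[k] += acc;
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// Empirical-mode decomposition: sifting with natural cubic-spline envelopes
// through local extrema (mirror-extended at the edges).
// ---------------------------------------------------------------------------

static void natural_spline(const std::vector<double> &xs,
                           const std::vector<double> &ys, int n,
                           std::vector<double> &out) {
  const int m = (int)xs.size();
  out.assign(n, 0.0);
  if (m == 1) { std::fill(out.begin(), out.end(), ys[0]); return; }
  if (m == 2) {
    const double slope = (ys[1] - ys[0]) / (xs[1] - xs[0]);
    for (int i = 0; i < n; ++i) out[i] = ys[0] + slope * (i - xs[0]);
    return;
  }
  // second derivatives by tridiagonal solve (natural boundary conditions)
  std::vector<double> h(m - 1), alpha(m, 0.0), l(m), mu(m), z(m), c(m, 0.0);
  for (int i = 0; i < m - 1; ++i) h[i] = xs[i + 1] - xs[i];
  for (int i = 1; i < m - 1; ++i)
    alpha[i] = 3.0 * ((ys[i + 1] - ys[i]) / h[i] - (ys[i] - ys[i - 1]) / h[i - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int i = 1; i < m - 1; ++i) {
    l[i] = 2.0 * (xs[i + 1] - xs[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l[i];
    z[i] = (alpha[i] - h[i - 1] * z[i - 1]) / l[i];
  }
  l[m - 1] = 1.0; z[m - 1] = 0.0; c[m - 1] = 0.0;
  for (int i = m - 2; i >= 0; --i) c[i] = z[i] - mu[i] * c[i + 1];
  int seg = 0;
  for (int i = 0; i < n; ++i) {
    const double t = (double)i;
    while (seg < m - 2 && t > xs[seg + 1]) ++seg;
    const double dx = t - xs[seg];
    const double bcoef = (ys[seg + 1] - ys[seg]) / h[seg] -
      h[seg] * (c[seg + 1] + 2.0 * c[seg]) / 3.0;
    const double dcoef = (c[seg + 1] - c[seg]) / (3.0 * h[seg]);
    out[i] = ys[seg] + bcoef * dx + c[seg] * dx * dx + dcoef * dx * dx * dx;
  }
}

static void find_extrema(const std::vector<double> &x,
                         std::vector<int> &imax, std::vector<int> &imin) {
  imax.clear(); imin.clear();
  const int n = (int)x.size();
  for (int i = 1; i < n - 1; ++i) {
    if (x[i] > x[i - 1] && x[i] >= x[i + 1]) imax.push_back(i);
    else if (x[i] < x[i - 1] && x[i] <= x[i + 1]) imin.push_back(i);
  }
}

static void envelope(const std::vector<double> &x, const std::vector<int> &idx,
                     int n, std::vector<double> &env) {
  // mirror the outermost extrema across the signal ends
  std::vector<double> xs, ys;
  xs.push_back(-(double)idx.front()); ys.push_back(x[idx.front()]);
  for (int i : idx) { xs.push_back((double)i); ys.push_back(x[i]); }
  xs.push_back(2.0 * (n - 1) - idx.back()); ys.push_back(x[idx.back()]);
  natural_spline(xs, ys, n, env);
}

// one sifted IMF; returns false if the input is monotone / has too few extrema
static bool sift_imf(const std::vector<double> &x, std::vector<double> &imf,
                     int max_sift, double sd_thresh) {
  const int n = (int)x.size();
  std::vector<int> imax, imin;
  find_extrema(x, imax, imin);
  if ((int)imax.size() + (int)imin.size() < 3) return false;
  imf = x;
  std::vector<double> up, lo;
  for (int it = 0; it < max_sift; ++it) {
    find_extrema(imf, imax, imin);
    if (imax.size() < 2 || imin.size() < 2) break;
    envelope(imf, imax, n, up);
    envelope(imf, imin, n, lo);
    double num = 0.0, den = 0.0;
    for (int i = 0; i < n; ++i) {
      const double m = 0.5 * (up[i] + lo[i]);
      num += m * m; den += imf[i] * imf[i];
      imf[i] -= m;
    }
    if (den <= 0.0 || num / den < sd_thresh) break;
  }
  return true;
}

// [[Rcpp::export]]
List emd_c(NumericVector x, int max_imfs, int max_sift = 30,
           double sd_thresh = 0.05) {
  const int n = x.size();
  std::vector<double> resid(x.begin(), x.end()), imf;
  std::vector<std::vector<double> > imfs;
  for (int k = 0; k < max_imfs; ++k) {
    if (!sift_imf(resid, imf, max_sift, sd_thresh)) break;
    imfs.push_back(imf);
    for (int i = 0; i < n; ++i) resid[i] -= imf[i];
  }
  NumericMatrix im((int)imfs.size(), n);
  for (int k = 0; k < (int)imfs.size(); ++k)
    for (int i = 0; i < n; ++i) im(k, i) = imfs[k][i];
  return List::create(_["imfs"] = im,
                      _["residue"] = NumericVector(resid.begin(), resid.end()));
}

// first IMF only (used repeatedly inside the ensemble decomposition)
// [[Rcpp::export]]
NumericVector emd_first_imf(NumericVector x, int max_sift = 30,
                            double sd_thresh = 0.05) {
  std::vector<double> xv(x.begin(), x.end()), imf;
  if (!sift_imf(xv, imf, max_sift, sd_thresh))
    return NumericVector(x.size());  // no oscillation: first mode is zero
  return NumericVector(imf.begin(), imf.end());
}

// ---------------------------------------------------------------------------
// Sample entropy: template match counts with Chebyshev distance < r,
// self-matches excluded.  Returns counts A (m+1) and B (m).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // templates that can be extended to length m+1
  double A = 0.0, B = 0.0;
  const double *p = x.begin();
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        const double dd = std::fabs(p[i + k] - p[j + k]);
        if (dd > d) d = dd;
      }
      if (d < r) {
        B += 1.0;
        if (std::fabs(p[i + m] - p[j + m]) < r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}

// ---------------------------------------------------------------------------
// Fused elementwise kernels for the network: batch norm, ELU, channel-wise
// soft thresholding and global average pooling of |x|.  Layout (W, C, N).
// ---------------------------------------------------------------------------

// per-channel mean and mean of squares over (W, N)
// [[Rcpp::export]]
NumericMatrix ch_moments(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int W = d[0], C = d[1], N = d[2];
  NumericMatrix out(C, 2);
  const double *p = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xi = p + (size_t)n * W * C + (size_t)c * W;
      double s = 0, s2 = 0;
      for (int w = 0; w < W; ++w) { s += xi[w]; s2 += xi[w] * xi[w]; }
      out(c, 0) += s; out(c, 1) += s2;
    }
  const double m = (double)W * N;
  for (int c = 0; c < C; ++c) { out(c, 0) /= m; out(c, 1) /= m; }
  return out;
}

// y = gamma * xhat + beta with xhat = (x - mu) * ivar; returns list(xhat, y)
// [[Rcpp::export]]
List bn_affine(NumericVector x, NumericVector mu, NumericVector ivar,
               NumericVector gamma, NumericVector beta) {
  IntegerVector d = x.attr("dim");
  const int W = d[0], C = d[1], N = d[2];
  NumericVector xhat(x.size()), y(x.size());
  xhat.attr("dim") = d; y.attr("dim") = d;
  const double *p = x.begin();
  double *ph = xhat.begin(), *py = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)n * W * C + (size_t)c * W;
      const double m = mu[c], iv = ivar[c], g = gamma[c], b = beta[c];
      for (int w = 0; w < W; ++w) {
        const double h = (p[off + w] - m) * iv;
        ph[off + w] = h;
        py[off + w] = g * h + b;
      }
    }
  return List::create(_["xhat"] = xhat, _["y"] = y);
}

// per-channel sums of gy and gy * xhat
// [[Rcpp::export]]
NumericMatrix ch_sums2(NumericVector gy, NumericVector xhat) {
  IntegerVector d = gy.attr("dim");
  const int W = d[0], C = d[1], N = d[2];
  NumericMatrix out(C, 2);
  const double *pg = gy.begin(), *ph = xhat.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)n * W * C + (size_t)c * W;
      double s = 0, sh = 0;
      for (int w = 0; w < W; ++w) { s += pg[off + w]; sh += pg[off + w] * ph[off + w]; }
      out(c, 0) += s; out(c, 1) += sh;
    }
  return out;
}

// gx = coef_c * (gy - gb_c - xhat * gg_c)
// [[Rcpp::export]]
NumericVector bn_bwd_elem(NumericVector gy, NumericVector xhat,
                          NumericVector coef, NumericVector gb,
                          NumericVector gg) {
  IntegerVector d = gy.attr("dim");
  const int W = d[0], C = d[1], N = d[2];
  NumericVector gx(gy.size());
  gx.attr("dim") = d;
  const double *pg = gy.begin(), *ph = xhat.begin();
  double *po = gx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)n * W * C + (size_t)c * W;
      const double cf = coef[c], b = gb[c], g = gg[c];
      for (int w = 0; w < W; ++w)
        po[off + w] = cf * (pg[off + w] - b - ph[off + w] * g);
    }
  return gx;
}

// [[Rcpp::export]]
NumericVector elu_c(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i)
    y[i] = x[i] > 0 ? x[i] : std::expm1(x[i]);
  return y;
}

// gx = gy * elu'(x) computed from the forward output y
// [[Rcpp::export]]
NumericVector elu_bwd_c(NumericVector gy, NumericVector y) {
  NumericVector gx(gy.size());
  gx.attr("dim") = gy.attr("dim");
  for (R_xlen_t i = 0; i < gy.size(); ++i)
    gx[i] = y[i] >= 0 ? gy[i] : gy[i] * (y[i] + 1.0);
  return gx;
}

// per-(channel, sample) mean of |x| -> C x N
// [[Rcpp::export]]
NumericMatrix gap_abs_c(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int W = d[0], C = d[1], N = d[2];
  NumericMatrix out(C, N);
  const double *p = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)n * W * C + (size_t)c * W;
      double s = 0;
      for (int w = 0; w < W; ++w) s += std::fabs(p[off + w]);
      out(c, n) = s / W;
    }
  return out;
}

// soft thresholding with per-(channel, sample) thresholds tau (C x N)
// [[Rcpp::export]]
NumericVector soft_thr_c(NumericVector x, NumericMatrix tau) {
  IntegerVector d = x.attr("dim");
  const int W = d[0], C = d[1], N = d[2];
  NumericVector y(x.size());
  y.attr("dim") = d;
  const double *p = x.begin();
  double *py = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)n * W * C + (size_t)c * W;
      const double t = tau(c, n);
      for (int w = 0; w < W; ++w) {
        const double v = p[off + w];
        py[off + w] = v > t ? v - t : (v < -t ? v + t : 0.0);
      }
    }
  return y;
}

// backward of soft threshold + the |x|-GAP side path:
// gx = gy * 1{|x|>tau} + (sign(x)/W) * gU_cn ; gtau_cn = -sum sign(x) gy 1{|x|>tau}
// [[Rcpp::export]]
List soft_thr_bwd_c(NumericVector x, NumericMatrix tau, NumericVector gy,
                    NumericMatrix gU) {
  IntegerVector d = x.attr("dim");
  const int W = d[0], C = d[1], N = d[2];
  NumericVector gx(x.size());
  gx.attr("dim") = d;
  NumericMatrix gtau(C, N);
  const double *p = x.begin(), *pg = gy.begin();
  double *po = gx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)n * W * C + (size_t)c * W;
      const double t = tau(c, n), gu = gU(c, n) / W;
      double gt = 0;
      for (int w = 0; w < W; ++w) {
        const double v = p[off + w], g = pg[off + w];
        const double sgn = v > 0 ? 1.0 : (v < 0 ? -1.0 : 0.0);
        double out = sgn * gu;
        if (std::fabs(v) > t) { out += g; gt -= sgn * g; }
        po[off + w] = out;
      }
      gtau(c, n) = gt;
    }
  return List::create(_["gx"] = gx, _["gtau"] = gtau);
}
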