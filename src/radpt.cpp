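// Low-level image operators for the radiomics battery.
//
// Conventions shared with the R layer (and with the naive oracles in the
// test suite):
//  - matrices are indexed (row i, col j), 0-based here, 1-based in R;
//  - border handling for all sliding-window/convolution operators is
//    symmetric (half-sample) reflection: index -1 maps to 0, n maps to n-1;
//  - filtering is cross-correlation: out[i,j] = sum_k ker[a,b] *
//    img[i+a-ci, j+b-cj] with (ci,cj) the kernel centre;
//  - GLCM accumulation is symmetric over the four distance-1 offsets
//    {(0,1),(1,0),(1,1),(1,-1)}; entropies use natural log with 0*log0 = 0.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <limits>
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // symmetric (half-sample) reflection, valid for |i| < 2n
  if (i < 0) i = -i - 1;
  if (i >= n) i = 2 * n - i - 1;
  return i;
}

// [[Rcpp::export(name = ".conv2_reflect_cpp")]]
NumericMatrix conv2_reflect_cpp(NumericMatrix img, NumericMatrix ker) {
  const int nr = img.nrow(), nc = img.ncol();
  const int kr = ker.nrow(), kc = ker.ncol();
  const int ci = kr / 2, cj = kc / 2;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int b = 0; b < kc; ++b) {
        const int jj = reflect_idx(j + b - cj, nc);
        for (int a = 0; a < kr; ++a) {
          const int ii = reflect_idx(i + a - ci, nr);
          acc += ker(a, b) * img(ii, jj);
        }
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".gauss_smooth_cpp")]]
NumericMatrix gauss_smooth_cpp(NumericMatrix img, double sigma) {
  const int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  const int h = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * h + 1);
  double s = 0.0;
  for (int t = -h; t <= h; ++t) {
    k[t + h] = std::exp(-0.5 * (double)t * t / (sigma * sigma));
    s += k[t + h];
  }
  for (double &v : k) v /= s;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -h; t <= h; ++t) acc += k[t + h] * img(reflect_idx(i + t, nr), j);
      tmp(i, j) = acc;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -h; t <= h; ++t) acc += k[t + h] * tmp(i, reflect_idx(j + t, nc));
      out(i, j) = acc;
    }
  return out;
}

// ---- exact Euclidean distance transform (Felzenszwalb & Huttenlocher) ----

static void dt1d(const std::vector<double> &f, double s,
                 std::vector<double> &d) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  int q0 = 0;
  while (q0 < n && !std::isfinite(f[q0])) ++q0;
  if (q0 == n) {  // no finite source in this scan line
    std::fill(d.begin(), d.begin() + n, INF);
    return;
  }
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (!std::isfinite(f[q])) continue;
    double sq = (double)q * s, sv, num;
    while (true) {
      sv = (double)v[k] * s;
      num = ((f[q] + sq * sq) - (f[v[k]] + sv * sv)) / (2.0 * sq - 2.0 * sv);
      if (k > 0 && num <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = num;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double sq = (double)q * s;
    while (z[k + 1] < sq) ++k;
    double sv = (double)v[k] * s;
    d[q] = (sq - sv) * (sq - sv) + f[v[k]];
  }
}

// Distance (mm) from every pixel to the nearest nonzero mask pixel; 0 inside.
// [[Rcpp::export(name = ".edt_mm_cpp")]]
NumericMatrix edt_mm_cpp(IntegerMatrix mask, double sx, double sy) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  NumericMatrix g(nr, nc);
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  bool any = false;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      g(i, j) = mask(i, j) ? 0.0 : INF;
      if (mask(i, j)) any = true;
    }
  if (!any) {
    std::fill(g.begin(), g.end(), INF);
    return g;
  }
  // transform along rows (i varies, spacing sx)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = g(i, j);
    f.resize(nr); d.resize(nr);
    dt1d(f, sx, d);
    for (int i = 0; i < nr; ++i) g(i, j) = d[i];
  }
  // then along columns (j varies, spacing sy)
  for (int i = 0; i < nr; ++i) {
    f.resize(nc); d.resize(nc);
    for (int j = 0; j < nc; ++j) f[j] = g(i, j);
    dt1d(f, sy, d);
    for (int j = 0; j < nc; ++j) g(i, j) = std::sqrt(d[j]);
  }
  return g;
}

// ---- sliding-window first-order statistics ----

// [[Rcpp::export(name = ".window_stats_cpp")]]
List window_stats_cpp(NumericMatrix img, int w) {
  const int nr = img.nrow(), nc = img.ncol(), h = w / 2;
  NumericMatrix m(nr, nc), med(nr, nc), sd(nr, nc), rng(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)w * w);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      double s = 0.0, lo = R_PosInf, hi = R_NegInf;
      for (int b = -h; b <= h; ++b) {
        int jj = j + b;
        if (jj < 0 || jj >= nc) continue;  // border-clipped window
        for (int a = -h; a <= h; ++a) {
          int ii = i + a;
          if (ii < 0 || ii >= nr) continue;
          double v = img(ii, jj);
          buf.push_back(v);
          s += v;
          if (v < lo) lo = v;
          if (v > hi) hi = v;
        }
      }
      const int n = (int)buf.size();
      const double mu = s / n;
      double ss = 0.0;
      for (double v : buf) ss += (v - mu) * (v - mu);
      m(i, j) = mu;
      sd(i, j) = n > 1 ? std::sqrt(ss / (n - 1)) : 0.0;
      rng(i, j) = hi - lo;
      std::sort(buf.begin(), buf.end());
      med(i, j) = (n % 2) ? buf[n / 2] : 0.5 * (buf[n / 2 - 1] + buf[n / 2]);
    }
  }
  return List::create(_["mean"] = m, _["median"] = med, _["sd"] = sd,
                      _["range"] = rng);
}

// ---- GLCM accumulator and the 13 Haralick statistics ----

struct GlcmAcc {
  int L;
  std::vector<double> p, px, py, ps, pd;
  std::vector<int> tp, tx, ty, ts, td;
  double total;
  explicit GlcmAcc(int levels)
      : L(levels), p((size_t)levels * levels, 0.0), px(levels, 0.0),
        py(levels, 0.0), ps(2 * levels, 0.0), pd(levels, 0.0), total(0.0) {}
  inline void add(int i, int j) {
    // symmetric: count both (i,j) and (j,i)
    addone(i, j);
    addone(j, i);
  }
  inline void addone(int i, int j) {
    int idx = i * L + j;
    if (p[idx] == 0.0) tp.push_back(idx);
    p[idx] += 1.0;
    total += 1.0;
  }
  void finalize() {
    for (int idx : tp) p[idx] /= total;
    for (int idx : tp) {
      int i = idx / L, j = idx % L;
      double v = p[idx];
      if (px[i] == 0.0) tx.push_back(i);
      px[i] += v;
      if (py[j] == 0.0) ty.push_back(j);
      py[j] += v;
      if (ps[i + j] == 0.0) ts.push_back(i + j);
      ps[i + j] += v;
      int dk = i > j ? i - j : j - i;
      if (pd[dk] == 0.0) td.push_back(dk);
      pd[dk] += v;
    }
  }
  void stats(double *out) {
    double energy = 0, entropy = 0, contrast = 0, idm = 0, sij = 0;
    for (int idx : tp) {
      int i = idx / L, j = idx % L;
      double v = p[idx];
      energy += v * v;
      entropy -= v * std::log(v);
      double dij = (double)(i - j);
      contrast += dij * dij * v;
      idm += v / (1.0 + dij * dij);
      sij += (double)i * (double)j * v;
    }
    double mux = 0, muy = 0;
    for (int i : tx) mux += (double)i * px[i];
    for (int j : ty) muy += (double)j * py[j];
    double vx = 0, vy = 0, hx = 0, hy = 0;
    for (int i : tx) {
      vx += ((double)i - mux) * ((double)i - mux) * px[i];
      hx -= px[i] * std::log(px[i]);
    }
    for (int j : ty) {
      vy += ((double)j - muy) * ((double)j - muy) * py[j];
      hy -= py[j] * std::log(py[j]);
    }
    double corr = 0.0;
    double sdxy = std::sqrt(vx * vy);
    if (sdxy > 1e-12) corr = (sij - mux * muy) / sdxy;
    double sum_avg = 0, sum_var = 0, sum_ent = 0;
    for (int k : ts) sum_avg += (double)k * ps[k];
    for (int k : ts) {
      sum_var += ((double)k - sum_avg) * ((double)k - sum_avg) * ps[k];
      sum_ent -= ps[k] * std::log(ps[k]);
    }
    double mud = 0, dvar = 0, dent = 0;
    for (int k : td) mud += (double)k * pd[k];
    for (int k : td) {
      dvar += ((double)k - mud) * ((double)k - mud) * pd[k];
      dent -= pd[k] * std::log(pd[k]);
    }
    // HXY1 = -sum_ij p log(px py) and HXY2 = -sum_ij px py log(px py)
    // both reduce exactly to HX + HY (marginals of p sum to the marginal
    // distributions); the literal sums are kept in the R reference
    // implementation, which the tests compare against.
    double hxy1 = hx + hy, hxy2 = hx + hy;
    double denom = std::max(hx, hy);
    double imc1 = denom > 1e-12 ? (entropy - hxy1) / denom : 0.0;
    double imc2 = std::sqrt(std::max(0.0, 1.0 - std::exp(-2.0 * (hxy2 - entropy))));
    out[0] = energy;
    out[1] = entropy;
    out[2] = contrast;
    out[3] = corr;
    out[4] = vx;         // sum of squares: variance
    out[5] = idm;
    out[6] = sum_avg;
    out[7] = sum_var;
    out[8] = sum_ent;
    out[9] = dvar;
    out[10] = dent;
    out[11] = imc1;
    out[12] = imc2;
  }
  void reset() {
    for (int idx : tp) p[idx] = 0.0;
    for (int i : tx) px[i] = 0.0;
    for (int j : ty) py[j] = 0.0;
    for (int k : ts) ps[k] = 0.0;
    for (int k : td) pd[k] = 0.0;
    tp.clear(); tx.clear(); ty.clear(); ts.clear(); td.clear();
    total = 0.0;
  }
};

static const int OFF[4][2] = {{0, 1}, {1, 0}, {1, 1}, {1, -1}};

// Per-pixel windowed Haralick maps. For each ROI pixel, the window (clipped
// at the image border) is intersected with the ROI; the surviving pixels are
// min-max quantized to n_levels and pairs at the four distance-1 offsets
// (both pixels inside window-and-ROI) accumulate a symmetric GLCM.
// Returns (nr, nc, 13 * n_windows); NA outside the ROI or when no pair exists.
// [[Rcpp::export(name = ".haralick_maps_cpp")]]
NumericVector haralick_maps_cpp(NumericMatrix img, IntegerMatrix roi,
                                IntegerVector windows, int n_levels) {
  const int nr = img.nrow(), nc = img.ncol(), nw = windows.size();
  NumericVector out((size_t)nr * nc * 13 * nw, NA_REAL);
  out.attr("dim") = IntegerVector::create(nr, nc, 13 * nw);
  GlcmAcc acc(n_levels);
  const size_t plane = (size_t)nr * nc;
  std::vector<int> lev;  // local level buffer, row-major within window
  double st[13];
  for (int wi = 0; wi < nw; ++wi) {
    const int w = windows[wi], h = w / 2;
    lev.assign((size_t)w * w, -1);
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        if (!roi(i, j)) continue;
        // gather window & ROI, min/max
        double lo = R_PosInf, hi = R_NegInf;
        for (int b = -h; b <= h; ++b) {
          int jj = j + b;
          for (int a = -h; a <= h; ++a) {
            int ii = i + a;
            int k = (a + h) * w + (b + h);
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc || !roi(ii, jj)) {
              lev[k] = -1;
              continue;
            }
            double v = img(ii, jj);
            lev[k] = 0;  // provisional: in-window marker
            if (v < lo) lo = v;
            if (v > hi) hi = v;
          }
        }
        const double span = hi - lo;
        for (int b = -h; b <= h; ++b) {
          int jj = j + b;
          for (int a = -h; a <= h; ++a) {
            int k = (a + h) * w + (b + h);
            if (lev[k] < 0) continue;
            if (span <= 0) { lev[k] = 0; continue; }
            int q = (int)std::floor((img(i + a, jj) - lo) / span * n_levels);
            if (q >= n_levels) q = n_levels - 1;
            if (q < 0) q = 0;
            lev[k] = q;
          }
        }
        // accumulate pairs
        for (int a = 0; a < w; ++a) {
          for (int b = 0; b < w; ++b) {
            int l0 = lev[a * w + b];
            if (l0 < 0) continue;
            for (int o = 0; o < 4; ++o) {
              int a2 = a + OFF[o][0], b2 = b + OFF[o][1];
              if (a2 < 0 || a2 >= w || b2 < 0 || b2 >= w) continue;
              int l1 = lev[a2 * w + b2];
              if (l1 < 0) continue;
              acc.add(l0, l1);
            }
          }
        }
        if (acc.total > 0) {
          acc.finalize();
          acc.stats(st);
          for (int s = 0; s < 13; ++s)
            out[(size_t)(wi * 13 + s) * plane + (size_t)j * nr + i] = st[s];
        }
        acc.reset();
      }
    }
  }
  return out;
}

// Per-pixel dominant gradient orientation in [0, pi): the principal direction
// of the stacked (gx, gy) vectors over a border-clipped w x w window,
// obtained from the 2x2 structure tensor. Gradients are Sobel responses.
// [[Rcpp::export(name = ".collage_orientation_cpp")]]
NumericMatrix collage_orientation_cpp(NumericMatrix img, int w) {
  const int nr = img.nrow(), nc = img.ncol(), h = w / 2;
  NumericMatrix gx(nr, nc), gy(nr, nc), th(nr, nc);
  // Sobel, symmetric padding: gx = d/d(row index), gy = d/d(col index)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double sx = 0, sy = 0;
      static const int kx[3][3] = {{-1, -2, -1}, {0, 0, 0}, {1, 2, 1}};
      static const int ky[3][3] = {{-1, 0, 1}, {-2, 0, 2}, {-1, 0, 1}};
      for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b) {
          double v = img(reflect_idx(i + a, nr), reflect_idx(j + b, nc));
          sx += kx[a + 1][b + 1] * v;
          sy += ky[a + 1][b + 1] * v;
        }
      gx(i, j) = sx;
      gy(i, j) = sy;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double a = 0, b = 0, c = 0;
      for (int db = -h; db <= h; ++db) {
        int jj = j + db;
        if (jj < 0 || jj >= nc) continue;
        for (int da = -h; da <= h; ++da) {
          int ii = i + da;
          if (ii < 0 || ii >= nr) continue;
          double x = gx(ii, jj), y = gy(ii, jj);
          a += x * x;
          b += x * y;
          c += y * y;
        }
      }
      double theta = 0.0;
      if (a + c > 1e-24) {
        theta = 0.5 * std::atan2(2.0 * b, a - c);
        if (theta < 0) theta += M_PI;
        if (theta >= M_PI) theta -= M_PI;
      }
      th(i, j) = theta;
    }
  return th;
}

// CoLlAGe maps: co-occurrence (within window-and-ROI) of the quantized
// dominant-orientation map, summarized by the 13 Haralick statistics.
// Orientation bins are global equal-width bins over [0, pi).
// [[Rcpp::export(name = ".collage_maps_cpp")]]
NumericVector collage_maps_cpp(NumericMatrix img, IntegerMatrix roi, int w,
                               int n_bins) {
  const int nr = img.nrow(), nc = img.ncol(), h = w / 2;
  NumericMatrix th = collage_orientation_cpp(img, w);
  IntegerMatrix bins(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int q = (int)std::floor(th(i, j) / M_PI * n_bins);
      if (q >= n_bins) q = n_bins - 1;
      bins(i, j) = q;
    }
  NumericVector out((size_t)nr * nc * 13, NA_REAL);
  out.attr("dim") = IntegerVector::create(nr, nc, 13);
  GlcmAcc acc(n_bins);
  const size_t plane = (size_t)nr * nc;
  double st[13];
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!roi(i, j)) continue;
      for (int a = -h; a <= h; ++a) {
        int ii = i + a;
        if (ii < 0 || ii >= nr) continue;
        for (int b = -h; b <= h; ++b) {
          int jj = j + b;
          if (jj < 0 || jj >= nc || !roi(ii, jj)) continue;
          for (int o = 0; o < 4; ++o) {
            int i2 = ii + OFF[o][0], j2 = jj + OFF[o][1];
            if (i2 < i - h || i2 > i + h || j2 < j - h || j2 > j + h) continue;
            if (i2 < 0 || i2 >= nr || j2 < 0 || j2 >= nc || !roi(i2, j2)) continue;
            acc.add(bins(ii, jj), bins(i2, j2));
          }
        }
      }
      if (acc.total > 0) {
        acc.finalize();
        acc.stats(st);
        for (int s = 0; s < 13; ++s)
          out[(size_t)s * plane + (size_t)j * nr + i] = st[s];
      }
      acc.reset();
    }
  return out;
}
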