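// Low-level image kernels used by the preprocessing chain, the CLAHE
// equalizer and the speckle phantom renderer. All convolutions use
// reflect padding so that no artificial border edges are created (those
// would otherwise be deleted by the clear-border step together with true
// surface pixels).
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <algorithm>
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // reflect-101 style without repeating the edge sample twice would be
  // "101"; plain reflection (edge repeated) is what we document and use.
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable Gaussian smoothing with an explicitly truncated support.
// half_r / half_c give the half-extent of the kernel in rows / columns,
// so the full support is (2*half_r+1) x (2*half_c+1).
// [[Rcpp::export(name = ".cpp_gaussian_sep")]]
NumericMatrix cpp_gaussian_sep(NumericMatrix img, double sigma_r, double sigma_c,
                               int half_r, int half_c) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<double> kr(2 * half_r + 1), kc(2 * half_c + 1);
  double sr = 0.0, sc = 0.0;
  for (int i = -half_r; i <= half_r; ++i) {
    double w = (sigma_r > 0) ? std::exp(-0.5 * i * i / (sigma_r * sigma_r)) : (i == 0 ? 1.0 : 0.0);
    kr[i + half_r] = w; sr += w;
  }
  for (int j = -half_c; j <= half_c; ++j) {
    double w = (sigma_c > 0) ? std::exp(-0.5 * j * j / (sigma_c * sigma_c)) : (j == 0 ? 1.0 : 0.0);
    kc[j + half_c] = w; sc += w;
  }
  for (double &w : kr) w /= sr;
  for (double &w : kc) w /= sc;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  // vertical pass: contiguous within each column, fast interior loop
  for (int c = 0; c < nc; ++c) {
    const double *in = &img(0, c);
    double *o = &tmp(0, c);
    int lo = std::min(half_r, nr), hi = std::max(0, nr - half_r);
    for (int r = 0; r < lo; ++r) {
      double acc = 0.0;
      for (int i = -half_r; i <= half_r; ++i)
        acc += kr[i + half_r] * in[reflect_idx(r + i, nr)];
      o[r] = acc;
    }
    for (int r = lo; r < hi; ++r) {
      double acc = 0.0;
      const double *p = in + r - half_r;
      for (int i = 0; i <= 2 * half_r; ++i) acc += kr[i] * p[i];
      o[r] = acc;
    }
    for (int r = hi; r < nr; ++r) {
      if (r < lo) continue;
      double acc = 0.0;
      for (int i = -half_r; i <= half_r; ++i)
        acc += kr[i + half_r] * in[reflect_idx(r + i, nr)];
      o[r] = acc;
    }
  }
  // horizontal pass: accumulate whole columns (contiguous)
  for (int c = 0; c < nc; ++c) {
    double *o = &out(0, c);
    for (int j = -half_c; j <= half_c; ++j) {
      const double w = kc[j + half_c];
      const double *p = &tmp(0, reflect_idx(c + j, nc));
      for (int r = 0; r < nr; ++r) o[r] += w * p[r];
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_median_filter")]]
NumericMatrix cpp_median_filter(NumericMatrix img, int kh, int kw) {
  int nr = img.nrow(), nc = img.ncol();
  int hr = kh / 2, hc = kw / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)kh * kw);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      buf.clear();
      for (int j = -hc; j <= hc; ++j)
        for (int i = -hr; i <= hr; ++i)
          buf.push_back(img(reflect_idx(r + i, nr), reflect_idx(c + j, nc)));
      size_t m = buf.size() / 2;
      std::nth_element(buf.begin(), buf.begin() + m, buf.end());
      out(r, c) = buf[m];
    }
  return out;
}

// Sobel gradient magnitude (3x3), reflect padding.
// [[Rcpp::export(name = ".cpp_sobel_mag")]]
NumericMatrix cpp_sobel_mag(NumericMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double p[3][3];
      for (int i = -1; i <= 1; ++i)
        for (int j = -1; j <= 1; ++j)
          p[i + 1][j + 1] = img(reflect_idx(r + i, nr), reflect_idx(c + j, nc));
      double gy = (p[2][0] + 2 * p[2][1] + p[2][2]) - (p[0][0] + 2 * p[0][1] + p[0][2]);
      double gx = (p[0][2] + 2 * p[1][2] + p[2][2]) - (p[0][0] + 2 * p[1][0] + p[2][0]);
      out(r, c) = std::sqrt(gx * gx + gy * gy);
    }
  return out;
}

// Binary dilation/erosion by a structuring element given as a matrix of
// (drow, dcol) offsets (one row per element pixel).
// [[Rcpp::export(name = ".cpp_morph")]]
LogicalMatrix cpp_morph(LogicalMatrix mask, IntegerMatrix offsets, bool dilate) {
  int nr = mask.nrow(), nc = mask.ncol(), k = offsets.nrow();
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      bool v = !dilate;
      for (int e = 0; e < k; ++e) {
        int rr = r + offsets(e, 0), cc = c + offsets(e, 1);
        bool px = (rr >= 0 && rr < nr && cc >= 0 && cc < nc) ? (bool)mask(rr, cc) : false;
        if (dilate) { if (px) { v = true; break; } }
        else        { if (!px) { v = false; break; } }
      }
      out(r, c) = v;
    }
  return out;
}

// Remove 8-connected foreground components that touch the image border.
// [[Rcpp::export(name = ".cpp_clear_border")]]
LogicalMatrix cpp_clear_border(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out = clone(mask);
  std::vector<char> kill((size_t)nr * nc, 0);
  std::queue<std::pair<int, int> > q;
  auto push = [&](int r, int c) {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return;
    size_t idx = (size_t)c * nr + r;
    if (!kill[idx] && out(r, c)) { kill[idx] = 1; q.push(std::make_pair(r, c)); }
  };
  for (int c = 0; c < nc; ++c) { push(0, c); push(nr - 1, c); }
  for (int r = 0; r < nr; ++r) { push(r, 0); push(r, nc - 1); }
  while (!q.empty()) {
    std::pair<int, int> p = q.front(); q.pop();
    for (int i = -1; i <= 1; ++i)
      for (int j = -1; j <= 1; ++j)
        if (i || j) push(p.first + i, p.second + j);
  }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (kill[(size_t)c * nr + r]) out(r, c) = false;
  return out;
}

// Contrast-limited adaptive histogram equalization on an 8-bit image.
// `tile` is the tile side in pixels; clip is the normalized clip limit
// (fraction of the tile pixel count per histogram bin). Tile mappings are
// blended bilinearly between the four neighboring tile centers.
// [[Rcpp::export(name = ".cpp_clahe")]]
NumericMatrix cpp_clahe(NumericMatrix img, int tile_r, int tile_c, double clip) {
  int nr = img.nrow(), nc = img.ncol();
  int ntr = std::max(1, (nr + tile_r - 1) / tile_r);
  int ntc = std::max(1, (nc + tile_c - 1) / tile_c);
  const int nbins = 256;
  // per-tile clipped CDF mapping: map[tile][bin] -> 0..255
  std::vector<double> map((size_t)ntr * ntc * nbins, 0.0);
  for (int tc = 0; tc < ntc; ++tc) {
    for (int tr = 0; tr < ntr; ++tr) {
      int r0 = tr * tile_r, r1 = std::min(nr, r0 + tile_r);
      int c0 = tc * tile_c, c1 = std::min(nc, c0 + tile_c);
      double hist[nbins] = {0};
      int npx = 0;
      for (int c = c0; c < c1; ++c)
        for (int r = r0; r < r1; ++r) {
          int b = (int)std::round(img(r, c));
          b = std::min(255, std::max(0, b));
          hist[b] += 1.0; ++npx;
        }
      double limit = std::max(1.0, clip * npx);
      double excess = 0.0;
      for (int b = 0; b < nbins; ++b)
        if (hist[b] > limit) { excess += hist[b] - limit; hist[b] = limit; }
      double redist = excess / nbins;
      for (int b = 0; b < nbins; ++b) hist[b] += redist;
      double cdf = 0.0;
      double *m = &map[((size_t)tc * ntr + tr) * nbins];
      for (int b = 0; b < nbins; ++b) {
        cdf += hist[b];
        m[b] = 255.0 * cdf / npx;
      }
    }
  }
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    double tcf = (c + 0.5) / tile_c - 0.5;
    int tc0 = (int)std::floor(tcf);
    double wc = tcf - tc0;
    int tcA = std::min(ntc - 1, std::max(0, tc0));
    int tcB = std::min(ntc - 1, std::max(0, tc0 + 1));
    for (int r = 0; r < nr; ++r) {
      double trf = (r + 0.5) / tile_r - 0.5;
      int tr0 = (int)std::floor(trf);
      double wr = trf - tr0;
      int trA = std::min(ntr - 1, std::max(0, tr0));
      int trB = std::min(ntr - 1, std::max(0, tr0 + 1));
      int b = (int)std::round(img(r, c));
      b = std::min(255, std::max(0, b));
      double vAA = map[((size_t)tcA * ntr + trA) * nbins + b];
      double vAB = map[((size_t)tcA * ntr + trB) * nbins + b];
      double vBA = map[((size_t)tcB * ntr + trA) * nbins + b];
      double vBB = map[((size_t)tcB * ntr + trB) * nbins + b];
      out(r, c) = (1 - wr) * ((1 - wc) * vAA + wc * vBA) + wr * ((1 - wc) * vAB + wc * vBB);
    }
  }
  return out;
}

// Accumulate Gaussian point-spread stamps for a set of scatterers.
// Positions are 1-based fractional pixel coordinates (row, col).
// [[Rcpp::export(name = ".cpp_splat_gaussians")]]
NumericMatrix cpp_splat_gaussians(NumericVector row_px, NumericVector col_px,
                                  NumericVector amp, int nr, int nc,
                                  double sigma_ax, double sigma_lat) {
  NumericMatrix out(nr, nc);
  int hr = (int)std::ceil(3.0 * sigma_ax);
  int hc = (int)std::ceil(3.0 * sigma_lat);
  double inv2sa = 1.0 / (2.0 * sigma_ax * sigma_ax);
  double inv2sl = 1.0 / (2.0 * sigma_lat * sigma_lat);
  int n = row_px.size();
  for (int k = 0; k < n; ++k) {
    double r0 = row_px[k] - 1.0, c0 = col_px[k] - 1.0, a = amp[k];
    int rlo = std::max(0, (int)std::floor(r0) - hr);
    int rhi = std::min(nr - 1, (int)std::ceil(r0) + hr);
    int clo = std::max(0, (int)std::floor(c0) - hc);
    int chi = std::min(nc - 1, (int)std::ceil(c0) + hc);
    for (int c = clo; c <= chi; ++c) {
      double dc = c - c0;
      double wc = std::exp(-dc * dc * inv2sl);
      for (int r = rlo; r <= rhi; ++r) {
        double dr = r - r0;
        out(r, c) += a * wc * std::exp(-dr * dr * inv2sa);
      }
    }
  }
  return out;
}

// Bilinear sampling of img at fractional 1-based coordinates; out-of-range
// queries clamp to the border (used for PIV window deformation).
// [[Rcpp::export(name = ".cpp_bilinear_sample")]]
NumericVector cpp_bilinear_sample(NumericMatrix img, NumericVector row_q, NumericVector col_q) {
  int nr = img.nrow(), nc = img.ncol(), n = row_q.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    double r = row_q[k] - 1.0, c = col_q[k] - 1.0;
    if (r < 0) r = 0; if (r > nr - 1) r = nr - 1;
    if (c < 0) c = 0; if (c > nc - 1) c = nc - 1;
    int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
    int r1 = std::min(nr - 1, r0 + 1), c1 = std::min(nc - 1, c0 + 1);
    double fr = r - r0, fc = c - c0;
    out[k] = (1 - fr) * ((1 - fc) * img(r0, c0) + fc * img(r0, c1)) +
             fr * ((1 - fc) * img(r1, c0) + fc * img(r1, c1));
  }
  return out;
}
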