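// 3D voxel geometry kernels: anisotropic Euclidean feature transform,
// 6-connected component labelling, hole filling, separable Gaussian blur.
// Arrays are R arrays with dim = c(nx, ny, nz), x fastest.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D lower-envelope squared distance transform along one axis with physical
// spacing w, propagating the index of the nearest site (Felzenszwalb &
// Huttenlocher 2012, extended with feature tracking and infinite inputs).
static void dt1d(const std::vector<double>& f, const std::vector<int>& feat,
                 double w, std::vector<double>& out, std::vector<int>& outfeat,
                 std::vector<int>& v, std::vector<double>& z) {
  const int n = (int)f.size();
  const double w2 = w * w;
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    double s;
    while (true) {
      if (k < 0) { s = -INF; break; }
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    if (k + 1 < (int)z.size()) z[k + 1] = INF;
  }
  if (k < 0) { // no finite parabola on this scan line
    for (int i = 0; i < n; ++i) { out[i] = INF; outfeat[i] = -1; }
    return;
  }
  int j = 0;
  for (int i = 0; i < n; ++i) {
    while (j < k && z[j + 1] < i) ++j;
    double d = (double)(i - v[j]);
    out[i] = w2 * d * d + f[v[j]];
    outfeat[i] = feat[v[j]];
  }
}

// Squared-distance feature transform toward `sites` (logical array).
// Returns per voxel the distance in physical units to the nearest site voxel
// centre and the 1-based linear index of that site (NA if no sites).
// [[Rcpp::export]]
List cpp_edt_feature(LogicalVector sites, IntegerVector dims,
                     NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> d2(n);
  std::vector<int> feat(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (sites[i] == TRUE) { d2[i] = 0.0; feat[i] = (int)i; }
    else { d2[i] = INF; feat[i] = -1; }
  }
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), out(nmax), z(nmax + 1);
  std::vector<int> ft(nmax), outft(nmax), v(nmax);

  // pass along x
  for (int zc = 0; zc < nz; ++zc)
    for (int yc = 0; yc < ny; ++yc) {
      R_xlen_t base = (R_xlen_t)nx * (yc + (R_xlen_t)ny * zc);
      for (int i = 0; i < nx; ++i) { f[i] = d2[base + i]; ft[i] = feat[base + i]; }
      f.resize(nx); ft.resize(nx); out.resize(nx); outft.resize(nx);
      dt1d(f, ft, spacing[0], out, outft, v, z);
      for (int i = 0; i < nx; ++i) { d2[base + i] = out[i]; feat[base + i] = outft[i]; }
      f.resize(nmax); ft.resize(nmax); out.resize(nmax); outft.resize(nmax);
    }
  // pass along y
  for (int zc = 0; zc < nz; ++zc)
    for (int xc = 0; xc < nx; ++xc) {
      R_xlen_t base = xc + (R_xlen_t)nx * ny * zc;
      f.resize(ny); ft.resize(ny); out.resize(ny); outft.resize(ny);
      for (int i = 0; i < ny; ++i) {
        f[i] = d2[base + (R_xlen_t)nx * i]; ft[i] = feat[base + (R_xlen_t)nx * i];
      }
      dt1d(f, ft, spacing[1], out, outft, v, z);
      for (int i = 0; i < ny; ++i) {
        d2[base + (R_xlen_t)nx * i] = out[i]; feat[base + (R_xlen_t)nx * i] = outft[i];
      }
      f.resize(nmax); ft.resize(nmax); out.resize(nmax); outft.resize(nmax);
    }
  // pass along z
  const R_xlen_t stridez = (R_xlen_t)nx * ny;
  for (int yc = 0; yc < ny; ++yc)
    for (int xc = 0; xc < nx; ++xc) {
      R_xlen_t base = xc + (R_xlen_t)nx * yc;
      f.resize(nz); ft.resize(nz); out.resize(nz); outft.resize(nz);
      for (int i = 0; i < nz; ++i) {
        f[i] = d2[base + stridez * i]; ft[i] = feat[base + stridez * i];
      }
      dt1d(f, ft, spacing[2], out, outft, v, z);
      for (int i = 0; i < nz; ++i) {
        d2[base + stridez * i] = out[i]; feat[base + stridez * i] = outft[i];
      }
      f.resize(nmax); ft.resize(nmax); out.resize(nmax); outft.resize(nmax);
    }

  NumericVector dist(n);
  IntegerVector nearest(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (feat[i] < 0) { dist[i] = NA_REAL; nearest[i] = NA_INTEGER; }
    else { dist[i] = std::sqrt(d2[i]); nearest[i] = feat[i] + 1; }
  }
  dist.attr("dim") = dims;
  nearest.attr("dim") = dims;
  return List::create(_["dist"] = dist, _["nearest"] = nearest);
}

// 6-connected component labelling of a logical 3D array.
// Labels are assigned in raster-scan order of the first voxel encountered,
// giving a deterministic labelling.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i] != TRUE || lab[i] != 0) continue;
    ++cur;
    stack.push_back(i);
    lab[i] = cur;
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int x = (int)(p % nx), y = (int)((p / nx) % ny), zc = (int)(p / sz);
      R_xlen_t nb[6]; int nn = 0;
      if (x > 0) nb[nn++] = p - sx;
      if (x < nx - 1) nb[nn++] = p + sx;
      if (y > 0) nb[nn++] = p - sy;
      if (y < ny - 1) nb[nn++] = p + sy;
      if (zc > 0) nb[nn++] = p - sz;
      if (zc < nz - 1) nb[nn++] = p + sz;
      for (int q = 0; q < nn; ++q) {
        R_xlen_t j = nb[q];
        if (mask[j] == TRUE && lab[j] == 0) { lab[j] = cur; stack.push_back(j); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Fill interior cavities: background components not touching the array border
// become foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector inv(n);
  for (R_xlen_t i = 0; i < n; ++i) inv[i] = (mask[i] == TRUE) ? FALSE : TRUE;
  IntegerVector lab = cpp_label3d(inv, dims);
  std::vector<bool> touches(1, false);
  auto mark = [&](R_xlen_t i) {
    int l = lab[i];
    if (l > 0) {
      if ((int)touches.size() <= l) touches.resize(l + 1, false);
      touches[l] = true;
    }
  };
  for (int zc = 0; zc < nz; ++zc)
    for (int yc = 0; yc < ny; ++yc)
      for (int xc = 0; xc < nx; ++xc)
        if (xc == 0 || xc == nx - 1 || yc == 0 || yc == ny - 1 ||
            zc == 0 || zc == nz - 1)
          mark(xc + (R_xlen_t)nx * (yc + (R_xlen_t)ny * zc));
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int l = lab[i];
    bool bg_outside = l > 0 && l < (int)touches.size() && touches[l];
    out[i] = (mask[i] == TRUE || (l > 0 && !bg_outside)) ? TRUE : FALSE;
  }
  out.attr("dim") = dims;
  return out;
}

// Separable Gaussian blur with per-axis sigma in voxel units; edge clamping.
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector img, IntegerVector dims,
                          NumericVector sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(img.begin(), img.end()), b(n);
  const int dimlen[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, nx, (R_xlen_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2 * r + 1);
    double sum = 0;
    for (int i = -r; i <= r; ++i) {
      ker[i + r] = std::exp(-0.5 * i * i / (s * s));
      sum += ker[i + r];
    }
    for (double& kv : ker) kv /= sum;
    int len = dimlen[ax];
    R_xlen_t st = stride[ax];
    // iterate over all lines along axis ax
    int d1 = (ax == 0) ? 1 : 0;
    int d2 = (ax == 2) ? 1 : 2;
    for (int j2 = 0; j2 < dimlen[d2]; ++j2)
      for (int j1 = 0; j1 < dimlen[d1]; ++j1) {
        R_xlen_t base = stride[d1] * j1 + stride[d2] * j2;
        for (int i = 0; i < len; ++i) {
          double acc = 0;
          for (int kk = -r; kk <= r; ++kk) {
            int ii = i + kk;
            if (ii < 0) ii = 0;
            if (ii >= len) ii = len - 1;
            acc += ker[kk + r] * a[base + st * ii];
          }
          b[base + st * i] = acc;
        }
      }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}
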