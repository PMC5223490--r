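#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Voxel (i,j,k) [0-based] of an nx*ny*nz array stored column-major maps to
// linear index i + nx*(j + ny*k), matching R's array layout.

static inline R_xlen_t lin(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// ---- separable convolution with edge renormalisation ------------------------

static void conv_axis(std::vector<double> &x, int nx, int ny, int nz,
                      const NumericVector &w, int axis) {
  int half = (w.size() - 1) / 2;
  if (half == 0) return;
  int n = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  std::vector<double> line(n), out(n);
  for (int a = 0; a < ((axis == 0) ? ny : nx); ++a) {
    for (int b = 0; b < ((axis == 2) ? ny : nz); ++b) {
      // gather line
      for (int t = 0; t < n; ++t) {
        int i = (axis == 0) ? t : a;
        int j = (axis == 1) ? t : ((axis == 0) ? a : b);
        int k = (axis == 2) ? t : b;
        line[t] = x[lin(i, j, k, nx, ny)];
      }
      for (int t = 0; t < n; ++t) {
        double s = 0.0, ws = 0.0;
        int lo = std::max(0, t - half), hi = std::min(n - 1, t + half);
        for (int u = lo; u <= hi; ++u) {
          double wk = w[u - t + half];
          s += wk * line[u];
          ws += wk;
        }
        out[t] = s / ws;
      }
      for (int t = 0; t < n; ++t) {
        int i = (axis == 0) ? t : a;
        int j = (axis == 1) ? t : ((axis == 0) ? a : b);
        int k = (axis == 2) ? t : b;
        x[lin(i, j, k, nx, ny)] = out[t];
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_sep(NumericVector x, IntegerVector dim, List kernels) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> buf(x.begin(), x.end());
  for (int a = 0; a < 3; ++a) {
    NumericVector w = kernels[a];
    conv_axis(buf, nx, ny, nz, w, a);
  }
  NumericVector out(buf.begin(), buf.end());
  return out;
}

// ---- generic resampling under an affine (rigid) pull-back map ---------------

static inline double sample_volume(const NumericVector &x, int nx, int ny, int nz,
                                   double cx, double cy, double cz,
                                   bool linear, double background) {
  if (linear) {
    // clamp within the half-voxel border so the physical extent is covered;
    // beyond it, return the background
    if (cx < -0.5 || cy < -0.5 || cz < -0.5 || cx > nx - 0.5 || cy > ny - 0.5 ||
        cz > nz - 0.5)
      return background;
    if (cx < 0) cx = 0;
    if (cy < 0) cy = 0;
    if (cz < 0) cz = 0;
    if (cx > nx - 1) cx = nx - 1;
    if (cy > ny - 1) cy = ny - 1;
    if (cz > nz - 1) cz = nz - 1;
    int i0 = (int)std::floor(cx), j0 = (int)std::floor(cy), k0 = (int)std::floor(cz);
    if (i0 == nx - 1) i0--;
    if (j0 == ny - 1) j0--;
    if (k0 == nz - 1) k0--;
    if (i0 < 0) i0 = 0;
    if (j0 < 0) j0 = 0;
    if (k0 < 0) k0 = 0;
    double fx = cx - i0, fy = cy - j0, fz = cz - k0;
    double v = 0.0;
    for (int dk = 0; dk <= 1; ++dk)
      for (int dj = 0; dj <= 1; ++dj)
        for (int di = 0; di <= 1; ++di) {
          double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
          if (w > 0) v += w * x[lin(i0 + di, j0 + dj, k0 + dk, nx, ny)];
        }
    return v;
  } else {
    int i = (int)std::floor(cx + 0.5), j = (int)std::floor(cy + 0.5),
        k = (int)std::floor(cz + 0.5);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return background;
    return x[lin(i, j, k, nx, ny)];
  }
}

// M is a 3x4 matrix mapping output physical coordinates to input physical
// coordinates (pull-back convention).
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector x, IntegerVector dim,
                                  NumericVector spacing, NumericVector origin,
                                  IntegerVector odim, NumericVector ospacing,
                                  NumericVector oorigin, NumericMatrix M,
                                  bool linear, double background) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ox = odim[0], oy = odim[1], oz = odim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  R_xlen_t idx = 0;
  for (int k = 0; k < oz; ++k) {
    double pz = oorigin[2] + k * ospacing[2];
    for (int j = 0; j < oy; ++j) {
      double py = oorigin[1] + j * ospacing[1];
      for (int i = 0; i < ox; ++i, ++idx) {
        double px = oorigin[0] + i * ospacing[0];
        double qx = M(0, 0) * px + M(0, 1) * py + M(0, 2) * pz + M(0, 3);
        double qy = M(1, 0) * px + M(1, 1) * py + M(1, 2) * pz + M(1, 3);
        double qz = M(2, 0) * px + M(2, 1) * py + M(2, 2) * pz + M(2, 3);
        out[idx] = sample_volume(x, nx, ny, nz,
                                 (qx - origin[0]) / spacing[0],
                                 (qy - origin[1]) / spacing[1],
                                 (qz - origin[2]) / spacing[2],
                                 linear, background);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_interp_points(NumericVector x, IntegerVector dim,
                                NumericVector spacing, NumericVector origin,
                                NumericMatrix pts, bool linear, double background) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = pts.nrow();
  NumericVector out(n);
  for (int t = 0; t < n; ++t) {
    out[t] = sample_volume(x, nx, ny, nz,
                           (pts(t, 0) - origin[0]) / spacing[0],
                           (pts(t, 1) - origin[1]) / spacing[1],
                           (pts(t, 2) - origin[2]) / spacing[2],
                           linear, background);
  }
  return out;
}

// ---- squared Euclidean distance transform (Felzenszwalb & Huttenlocher) -----

static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n,
                 double s, std::vector<int> &v, std::vector<double> &z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double qq = (double)q * s;
    double sep;
    while (true) {
      double vv = (double)v[k] * s;
      sep = (f[q] + qq * qq - f[v[k]] - vv * vv) / (2 * qq - 2 * vv);
      if (sep <= z[k]) { k--; } else break;
    }
    k++;
    v[k] = q;
    z[k] = sep;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = (double)q * s;
    while (z[k + 1] < qq) k++;
    double vv = (double)v[k] * s;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
}

// Squared distance (mm^2) from every voxel to the nearest foreground voxel.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(IntegerVector mask, IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = 1e30;
  std::vector<double> d(n);
  for (R_xlen_t t = 0; t < n; ++t) d[t] = mask[t] ? 0.0 : INF;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), g(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = d[lin(i, j, k, nx, ny)];
      dt1d(f, g, nx, spacing[0], v, z);
      for (int i = 0; i < nx; ++i) d[lin(i, j, k, nx, ny)] = g[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = d[lin(i, j, k, nx, ny)];
      dt1d(f, g, ny, spacing[1], v, z);
      for (int j = 0; j < ny; ++j) d[lin(i, j, k, nx, ny)] = g[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = d[lin(i, j, k, nx, ny)];
      dt1d(f, g, nz, spacing[2], v, z);
      for (int k = 0; k < nz; ++k) d[lin(i, j, k, nx, ny)] = g[k];
    }
  NumericVector out(d.begin(), d.end());
  return out;
}

// ---- binary morphology ------------------------------------------------------

// offs: K x 3 integer offsets of the structuring element (includes origin).
// Outside the volume counts as background.
// [[Rcpp::export]]
IntegerVector cpp_morph(IntegerVector mask, IntegerVector dim, IntegerMatrix offs,
                        bool dilate) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int K = offs.nrow();
  IntegerVector out((R_xlen_t)nx * ny * nz);
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        int val = dilate ? 0 : 1;
        for (int t = 0; t < K; ++t) {
          int ii = i + offs(t, 0), jj = j + offs(t, 1), kk = k + offs(t, 2);
          int m = 0;
          if (ii >= 0 && jj >= 0 && kk >= 0 && ii < nx && jj < ny && kk < nz)
            m = mask[lin(ii, jj, kk, nx, ny)];
          if (dilate) {
            if (m) { val = 1; break; }
          } else {
            if (!m) { val = 0; break; }
          }
        }
        out[idx] = val;
      }
  return out;
}

// ---- connected components (6-connectivity) ---------------------------------

// [[Rcpp::export]]
List cpp_cc_label(IntegerVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<double> sizes;
  std::vector<R_xlen_t> stack;
  int nlab = 0;
  const int di[6] = {1, -1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, 1, -1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, 1, -1};
  for (R_xlen_t t = 0; t < n; ++t) {
    if (!mask[t] || lab[t]) continue;
    nlab++;
    double sz = 0;
    stack.push_back(t);
    lab[t] = nlab;
    while (!stack.empty()) {
      R_xlen_t c = stack.back();
      stack.pop_back();
      sz += 1;
      int i = (int)(c % nx);
      int j = (int)((c / nx) % ny);
      int k = (int)(c / ((R_xlen_t)nx * ny));
      for (int d = 0; d < 6; ++d) {
        int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        R_xlen_t q = lin(ii, jj, kk, nx, ny);
        if (mask[q] && !lab[q]) {
          lab[q] = nlab;
          stack.push_back(q);
        }
      }
    }
    sizes.push_back(sz);
  }
  return List::create(_["labels"] = lab, _["sizes"] = NumericVector(sizes.begin(), sizes.end()));
}

// ---- local neighborhood standard deviation ----------------------------------

// Population SD in the cubic (2r+1)^3 neighborhood, for voxels whose full
// neighborhood lies inside the mask (and the volume).
// [[Rcpp::export]]
List cpp_local_sd(NumericVector x, IntegerVector mask, IntegerVector dim, int r) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector valid(n);
  NumericVector sd(n, NA_REAL);
  int m = (2 * r + 1) * (2 * r + 1) * (2 * r + 1);
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        if (!mask[idx]) continue;
        if (i < r || j < r || k < r || i >= nx - r || j >= ny - r || k >= nz - r)
          continue;
        bool ok = true;
        double s = 0.0, s2 = 0.0;
        for (int dk = -r; dk <= r && ok; ++dk)
          for (int dj = -r; dj <= r && ok; ++dj)
            for (int di = -r; di <= r; ++di) {
              R_xlen_t q = lin(i + di, j + dj, k + dk, nx, ny);
              if (!mask[q]) { ok = false; break; }
              double v = x[q];
              s += v;
              s2 += v * v;
            }
        if (!ok) continue;
        valid[idx] = true;
        double mean = s / m;
        double var = s2 / m - mean * mean;
        sd[idx] = var > 0 ? std::sqrt(var) : 0.0;
      }
  return List::create(_["valid"] = valid, _["sd"] = sd);
}

// ---- structure-tensor anisotropy --------------------------------------------

static void eig_sym3(double a11, double a22, double a33, double a12, double a13,
                     double a23, double &emin, double &emax) {
  double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  double q = (a11 + a22 + a33) / 3.0;
  double p2 = (a11 - q) * (a11 - q) + (a22 - q) * (a22 - q) + (a33 - q) * (a33 - q) +
              2.0 * p1;
  if (p2 <= 0) { emin = emax = q; return; }
  double p = std::sqrt(p2 / 6.0);
  double b11 = (a11 - q) / p, b22 = (a22 - q) / p, b33 = (a33 - q) / p;
  double b12 = a12 / p, b13 = a13 / p, b23 = a23 / p;
  double detB = b11 * (b22 * b33 - b23 * b23) - b12 * (b12 * b33 - b23 * b13) +
                b13 * (b12 * b23 - b22 * b13);
  double rr = detB / 2.0;
  if (rr < -1.0) rr = -1.0;
  if (rr > 1.0) rr = 1.0;
  double phi = std::acos(rr) / 3.0;
  emax = q + 2.0 * p * std::cos(phi);
  emin = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
}

// Central-difference gradients (physical units); a gradient is defined where
// the voxel and its six axial neighbors are in the mask. The tensor at a voxel
// averages g g^T over the (2r+1)^3 neighborhood and requires every gradient in
// that neighborhood to be defined.
// [[Rcpp::export]]
List cpp_structure_aniso(NumericVector x, IntegerVector mask, IntegerVector dim,
                         NumericVector spacing, int r, double tol) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> gx(n), gy(n), gz(n);
  std::vector<char> gok(n, 0);
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        if (!mask[idx]) continue;
        if (i < 1 || j < 1 || k < 1 || i >= nx - 1 || j >= ny - 1 || k >= nz - 1)
          continue;
        R_xlen_t xp = lin(i + 1, j, k, nx, ny), xm = lin(i - 1, j, k, nx, ny);
        R_xlen_t yp = lin(i, j + 1, k, nx, ny), ym = lin(i, j - 1, k, nx, ny);
        R_xlen_t zp = lin(i, j, k + 1, nx, ny), zm = lin(i, j, k - 1, nx, ny);
        if (!mask[xp] || !mask[xm] || !mask[yp] || !mask[ym] || !mask[zp] || !mask[zm])
          continue;
        gok[idx] = 1;
        gx[idx] = (x[xp] - x[xm]) / (2.0 * spacing[0]);
        gy[idx] = (x[yp] - x[ym]) / (2.0 * spacing[1]);
        gz[idx] = (x[zp] - x[zm]) / (2.0 * spacing[2]);
      }
  LogicalVector valid(n);
  NumericVector aniso(n, NA_REAL);
  int m = (2 * r + 1) * (2 * r + 1) * (2 * r + 1);
  idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        if (!gok[idx]) continue;
        if (i < r || j < r || k < r || i >= nx - r || j >= ny - r || k >= nz - r)
          continue;
        bool ok = true;
        double sxx = 0, syy = 0, szz = 0, sxy = 0, sxz = 0, syz = 0;
        for (int dk = -r; dk <= r && ok; ++dk)
          for (int dj = -r; dj <= r && ok; ++dj)
            for (int di = -r; di <= r; ++di) {
              R_xlen_t q = lin(i + di, j + dj, k + dk, nx, ny);
              if (!gok[q]) { ok = false; break; }
              sxx += gx[q] * gx[q];
              syy += gy[q] * gy[q];
              szz += gz[q] * gz[q];
              sxy += gx[q] * gy[q];
              sxz += gx[q] * gz[q];
              syz += gy[q] * gz[q];
            }
        if (!ok) continue;
        valid[idx] = true;
        double emin, emax;
        eig_sym3(sxx / m, syy / m, szz / m, sxy / m, sxz / m, syz / m, emin, emax);
        if (emax <= tol) {
          aniso[idx] = 0.0;
        } else {
          if (emin < 0) emin = 0;
          aniso[idx] = 1.0 - emin / emax;
        }
      }
  return List::create(_["valid"] = valid, _["aniso"] = aniso);
}
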