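#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Continuous index of a physical coordinate on one axis.
static inline double cindex(double x, double origin, double spacing) {
  return (x - origin) / spacing;
}

// Trilinear interpolation of a 3D array (column-major, dims d) at points
// given in physical mm. Points outside the voxel-centre hull return
// `outside`. Used for dose resampling (outside = 0) and HU sampling
// (outside = -1000).
// [[Rcpp::export]]
NumericVector trilinear_sample_cpp(NumericVector arr, IntegerVector dims,
                                   NumericVector spacing, NumericVector origin,
                                   NumericMatrix pts, double outside) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = pts.nrow();
  NumericVector out(n);
  const double *a = REAL(arr);
  for (int i = 0; i < n; ++i) {
    double u = cindex(pts(i, 0), origin[0], spacing[0]);
    double v = cindex(pts(i, 1), origin[1], spacing[1]);
    double w = cindex(pts(i, 2), origin[2], spacing[2]);
    if (u < 0.0 || v < 0.0 || w < 0.0 ||
        u > nx - 1.0 || v > ny - 1.0 || w > nz - 1.0) {
      out[i] = outside;
      continue;
    }
    int i0 = (int)std::floor(u), j0 = (int)std::floor(v), k0 = (int)std::floor(w);
    if (i0 == nx - 1) i0--;
    if (j0 == ny - 1) j0--;
    if (k0 == nz - 1) k0--;
    if (i0 < 0) i0 = 0;
    if (j0 < 0) j0 = 0;
    if (k0 < 0) k0 = 0;
    double fx = u - i0, fy = v - j0, fz = w - k0;
    const int sxy = nx * ny;
    const double *base = a + i0 + nx * j0 + sxy * k0;
    double c000 = base[0], c100 = base[1];
    double c010 = base[nx], c110 = base[nx + 1];
    double c001 = base[sxy], c101 = base[sxy + 1];
    double c011 = base[sxy + nx], c111 = base[sxy + nx + 1];
    double c00 = c000 + fx * (c100 - c000);
    double c10 = c010 + fx * (c110 - c010);
    double c01 = c001 + fx * (c101 - c001);
    double c11 = c011 + fx * (c111 - c011);
    double c0 = c00 + fy * (c10 - c00);
    double c1 = c01 + fy * (c11 - c01);
    out[i] = c0 + fz * (c1 - c0);
  }
  return out;
}

// One-dimensional squared distance transform (Felzenszwalb & Huttenlocher),
// with sample spacing h. f holds squared distances on input and output.
static void dt1d(std::vector<double> &f, std::vector<int> &v,
                 std::vector<double> &z, double h) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double qq = (double)q * h, vv = (double)v[k] * h;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * qq - 2.0 * vv);
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  std::vector<double> d(n);
  for (int q = 0; q < n; ++q) {
    double qq = (double)q * h;
    while (z[k + 1] < qq) ++k;
    double vv = (double)v[k] * h;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
  f = d;
}

// Euclidean distance (mm) from every voxel to the nearest true voxel of a
// logical mask; 0 inside the mask. Anisotropic spacing supported.
// [[Rcpp::export]]
NumericVector edt_cpp(LogicalVector mask, IntegerVector dims,
                      NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  // large finite sentinel: infinities would produce INF-INF = NaN in the
  // parabola intersection; 1e20 dominates any realistic squared distance
  const double BIG = 1e20;
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i) g[i] = mask[i] ? 0.0 : BIG;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  // x lines
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t off = (R_xlen_t)nx * j + sxy * k;
      f.assign(g.begin() + off, g.begin() + off + nx);
      dt1d(f, v, z, spacing[0]);
      std::copy(f.begin(), f.end(), g.begin() + off);
    }
  // y lines
  f.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t off = i + sxy * k;
      for (int j = 0; j < ny; ++j) f[j] = g[off + (R_xlen_t)nx * j];
      dt1d(f, v, z, spacing[1]);
      for (int j = 0; j < ny; ++j) g[off + (R_xlen_t)nx * j] = f[j];
    }
  // z lines
  f.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t off = i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; ++k) f[k] = g[off + sxy * k];
      dt1d(f, v, z, spacing[2]);
      for (int k = 0; k < nz; ++k) g[off + sxy * k] = f[k];
    }
  NumericVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i) out[i] = std::sqrt(g[i]);
  return out;
}

// Radiological depth: line integral of relative electron density along the
// segment source -> point, by uniform-step midpoint ray marching restricted
// to the part of the segment inside the volume bounds (density outside the
// scanned volume is taken as 0, i.e. air). step is the marching step in mm.
// [[Rcpp::export]]
NumericVector radiological_depth_cpp(NumericVector dens, IntegerVector dims,
                                     NumericVector spacing, NumericVector origin,
                                     NumericVector source, NumericMatrix pts,
                                     double step) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = pts.nrow();
  NumericVector out(n);
  const double *a = REAL(dens);
  // outer bounds of the voxel volume (half a voxel beyond the centre hull)
  double lo[3], hi[3];
  for (int ax = 0; ax < 3; ++ax) {
    lo[ax] = origin[ax] - 0.5 * spacing[ax];
    int d = (ax == 0) ? nx : (ax == 1 ? ny : nz);
    hi[ax] = origin[ax] + (d - 0.5) * spacing[ax];
  }
  const int sxy = nx * ny;
  for (int p = 0; p < n; ++p) {
    double dir[3], L2 = 0.0;
    for (int ax = 0; ax < 3; ++ax) {
      dir[ax] = pts(p, ax) - source[ax];
      L2 += dir[ax] * dir[ax];
    }
    double L = std::sqrt(L2);
    if (L <= 0.0) {
      out[p] = 0.0;
      continue;
    }
    // slab clipping of t in [0, 1]
    double t0 = 0.0, t1 = 1.0;
    bool miss = false;
    for (int ax = 0; ax < 3; ++ax) {
      if (dir[ax] == 0.0) {
        if (source[ax] < lo[ax] || source[ax] > hi[ax]) { miss = true; break; }
      } else {
        double ta = (lo[ax] - source[ax]) / dir[ax];
        double tb = (hi[ax] - source[ax]) / dir[ax];
        if (ta > tb) std::swap(ta, tb);
        if (ta > t0) t0 = ta;
        if (tb < t1) t1 = tb;
        if (t0 > t1) { miss = true; break; }
      }
    }
    if (miss) {
      out[p] = 0.0;
      continue;
    }
    double seg = (t1 - t0) * L;
    if (seg <= 0.0) {
      out[p] = 0.0;
      continue;
    }
    int nstep = (int)std::ceil(seg / step);
    if (nstep < 1) nstep = 1;
    double h = seg / nstep;         // mm per step
    double dt = (t1 - t0) / nstep;  // param per step
    double acc = 0.0;
    for (int s = 0; s < nstep; ++s) {
      double t = t0 + (s + 0.5) * dt;
      double u = cindex(source[0] + t * dir[0], origin[0], spacing[0]);
      double v = cindex(source[1] + t * dir[1], origin[1], spacing[1]);
      double w = cindex(source[2] + t * dir[2], origin[2], spacing[2]);
      if (u < 0.0 || v < 0.0 || w < 0.0 ||
          u > nx - 1.0 || v > ny - 1.0 || w > nz - 1.0)
        continue;  // between outer bound and centre hull: treat as air
      int i0 = (int)std::floor(u), j0 = (int)std::floor(v), k0 = (int)std::floor(w);
      if (i0 == nx - 1) i0--;
      if (j0 == ny - 1) j0--;
      if (k0 == nz - 1) k0--;
      double fx = u - i0, fy = v - j0, fz = w - k0;
      const double *base = a + i0 + nx * j0 + sxy * k0;
      double c00 = base[0] + fx * (base[1] - base[0]);
      double c10 = base[nx] + fx * (base[nx + 1] - base[nx]);
      double c01 = base[sxy] + fx * (base[sxy + 1] - base[sxy]);
      double c11 = base[sxy + nx] + fx * (base[sxy + nx + 1] - base[sxy + nx]);
      double c0 = c00 + fy * (c10 - c00);
      double c1 = c01 + fy * (c11 - c01);
      acc += (c0 + fz * (c1 - c0)) * h;
    }
    out[p] = acc;
  }
  return out;
}
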