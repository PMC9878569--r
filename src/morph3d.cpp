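#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <functional>
using namespace Rcpp;

// 26-connected component labeling of a binary 3D mask.
// mask: integer vector of 0/1 in R array order, dims = c(nx, ny, nz).
// Returns integer labels (0 = background), components numbered from 1
// in order of first (column-major) encounter.
// [[Rcpp::export]]
IntegerVector label3d_cpp(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i] == 0 || lab[i] != 0) continue;
    ++cur;
    lab[i] = cur;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int z = (int)(v / ((R_xlen_t)nx * ny));
      int rem = (int)(v - (R_xlen_t)z * nx * ny);
      int y = rem / nx, x = rem % nx;
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz; if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy; if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int xx = x + dx; if (xx < 0 || xx >= nx) continue;
            R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
            if (mask[w] != 0 && lab[w] == 0) { lab[w] = cur; stack.push_back(w); }
          }
        }
      }
    }
  }
  lab.attr("ncomp") = cur;
  return lab;
}

// Separable Gaussian smoothing of a 3D volume with clamped boundaries.
// [[Rcpp::export]]
NumericVector gauss3d_cpp(NumericVector vol, IntegerVector dims, double sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (vol.size() != n) stop("volume length does not match dims");
  int rad = (int)std::ceil(3.0 * sigma);
  if (rad < 1) rad = 1;
  std::vector<double> k(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (auto &v : k) v /= s;

  std::vector<double> a(vol.begin(), vol.end()), b(n);
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  // pass along one axis: for each line, convolve with clamp
  auto pass = [&](int len, R_xlen_t stride, R_xlen_t nlines,
                  std::function<R_xlen_t(R_xlen_t)> base) {
    for (R_xlen_t l = 0; l < nlines; ++l) {
      R_xlen_t b0 = base(l);
      for (int i = 0; i < len; ++i) {
        double acc = 0.0;
        for (int j = -rad; j <= rad; ++j) {
          int ii = i + j;
          if (ii < 0) ii = 0; else if (ii >= len) ii = len - 1;
          acc += k[j + rad] * a[b0 + (R_xlen_t)ii * stride];
        }
        b[b0 + (R_xlen_t)i * stride] = acc;
      }
    }
    std::swap(a, b);
  };
  pass(nx, sx, (R_xlen_t)ny * nz, [&](R_xlen_t l) { return l * nx; });
  pass(ny, sy, (R_xlen_t)nx * nz, [&](R_xlen_t l) {
    R_xlen_t z = l / nx, x = l % nx; return z * sz + x; });
  pass(nz, sz, (R_xlen_t)nx * ny, [&](R_xlen_t l) { return l; });
  return NumericVector(a.begin(), a.end());
}

static inline double tri_area(const double *p, const double *q, const double *r) {
  double u[3] = { q[0] - p[0], q[1] - p[1], q[2] - p[2] };
  double v[3] = { r[0] - p[0], r[1] - p[1], r[2] - p[2] };
  double cx = u[1] * v[2] - u[2] * v[1];
  double cy = u[2] * v[0] - u[0] * v[2];
  double cz = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// Isosurface area of a scalar 3D field by marching tetrahedra.
// Each cell between eight voxel centers is split into six tetrahedra
// sharing the main diagonal; iso-crossing edges are found by linear
// interpolation. Returns total triangle area in voxel units.
// [[Rcpp::export]]
double march_tet_area_cpp(NumericVector vol, IntegerVector dims, double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  // cube vertex offsets, index = dx + 2*dy + 4*dz
  static const int off[8][3] = {
    {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}
  };
  // six tetrahedra around the 0-7 diagonal
  static const int tets[6][4] = {
    {0,1,3,7},{0,3,2,7},{0,2,6,7},{0,6,4,7},{0,4,5,7},{0,5,1,7}
  };
  double area = 0.0;
  double fv[8]; double pv[8][3];
  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        bool anyAbove = false, anyBelow = false;
        for (int v = 0; v < 8; ++v) {
          R_xlen_t idx = (R_xlen_t)(z + off[v][2]) * sz +
                         (R_xlen_t)(y + off[v][1]) * nx + (x + off[v][0]);
          fv[v] = vol[idx];
          pv[v][0] = x + off[v][0]; pv[v][1] = y + off[v][1]; pv[v][2] = z + off[v][2];
          if (fv[v] > level) anyAbove = true; else anyBelow = true;
        }
        if (!anyAbove || !anyBelow) continue;
        for (int t = 0; t < 6; ++t) {
          int ia[4]; int na = 0, nb = 0; int ib[4];
          for (int v = 0; v < 4; ++v) {
            int vi = tets[t][v];
            if (fv[vi] > level) ia[na++] = vi; else ib[nb++] = vi;
          }
          if (na == 0 || na == 4) continue;
          auto interp = [&](int p, int q, double *out) {
            double tt = (level - fv[p]) / (fv[q] - fv[p]);
            for (int d = 0; d < 3; ++d) out[d] = pv[p][d] + tt * (pv[q][d] - pv[p][d]);
          };
          if (na == 1 || na == 3) {
            int apex = (na == 1) ? ia[0] : ib[0];
            int *oth = (na == 1) ? ib : ia;
            double e0[3], e1[3], e2[3];
            interp(apex, oth[0], e0); interp(apex, oth[1], e1); interp(apex, oth[2], e2);
            area += tri_area(e0, e1, e2);
          } else { // 2-2: quad AC, AD, BD, BC
            double pac[3], pad[3], pbd[3], pbc[3];
            interp(ia[0], ib[0], pac); interp(ia[0], ib[1], pad);
            interp(ia[1], ib[1], pbd); interp(ia[1], ib[0], pbc);
            area += tri_area(pac, pad, pbd) + tri_area(pac, pbd, pbc);
          }
        }
      }
  return area;
}

// Exposed-face count of a binary mask: number of voxel faces between a
// foreground voxel and background (or the volume boundary).
// [[Rcpp::export]]
double exposed_faces_cpp(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  double faces = 0.0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = (R_xlen_t)z * sz + (R_xlen_t)y * nx + x;
        if (mask[i] == 0) continue;
        if (x == 0 || mask[i - 1] == 0) ++faces;
        if (x == nx - 1 || mask[i + 1] == 0) ++faces;
        if (y == 0 || mask[i - nx] == 0) ++faces;
        if (y == ny - 1 || mask[i + nx] == 0) ++faces;
        if (z == 0 || mask[i - sz] == 0) ++faces;
        if (z == nz - 1 || mask[i + sz] == 0) ++faces;
      }
  return faces;
}

// Gather x[idx] for an index matrix (1-based), returning a matrix-shaped
// vector in column-major order. Used by the convolution im2col step.
// [[Rcpp::export]]
NumericVector gather_cpp(NumericVector x, IntegerMatrix idx) {
  R_xlen_t nr = idx.nrow(), nc = idx.ncol();
  NumericVector out(nr * nc);
  for (R_xlen_t c = 0; c < nc; ++c)
    for (R_xlen_t r = 0; r < nr; ++r)
      out[c * nr + r] = x[idx(r, c) - 1];
  out.attr("dim") = IntegerVector::create((int)nr, (int)nc);
  return out;
}

// Scatter-add values of a matrix into a zero vector of length len at
// 1-based positions idx (duplicates accumulate). The col2im step.
// [[Rcpp::export]]
NumericVector scatter_add_cpp(NumericMatrix v, IntegerMatrix idx, int len) {
  NumericVector out(len);
  R_xlen_t nr = idx.nrow(), nc = idx.ncol();
  for (R_xlen_t c = 0; c < nc; ++c)
    for (R_xlen_t r = 0; r < nr; ++r)
      out[idx(r, c) - 1] += v(r, c);
  return out;
}
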