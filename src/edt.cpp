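#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Felzenszwalb & Huttenlocher squared Euclidean distance transform.
// One-dimensional pass; f holds squared distances so far, d receives result.
static void dt1d(const double *f, double *d, int n, int *v, double *z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

static void pass_axis(std::vector<double> &D, int nx, int ny, int nz, int axis) {
  int n = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  if (n <= 1) return;
  std::vector<double> f(n), d(n), z(n + 1);
  std::vector<int> v(n);
  if (axis == 0) {
    for (int zz = 0; zz < nz; ++zz)
      for (int yy = 0; yy < ny; ++yy) {
        double *p = &D[(size_t)zz * nx * ny + (size_t)yy * nx];
        dt1d(p, d.data(), n, v.data(), z.data());
        std::copy(d.begin(), d.end(), p);
      }
  } else if (axis == 1) {
    for (int zz = 0; zz < nz; ++zz)
      for (int xx = 0; xx < nx; ++xx) {
        for (int yy = 0; yy < ny; ++yy)
          f[yy] = D[(size_t)zz * nx * ny + (size_t)yy * nx + xx];
        dt1d(f.data(), d.data(), n, v.data(), z.data());
        for (int yy = 0; yy < ny; ++yy)
          D[(size_t)zz * nx * ny + (size_t)yy * nx + xx] = d[yy];
      }
  } else {
    for (int yy = 0; yy < ny; ++yy)
      for (int xx = 0; xx < nx; ++xx) {
        for (int zz = 0; zz < nz; ++zz)
          f[zz] = D[(size_t)zz * nx * ny + (size_t)yy * nx + xx];
        dt1d(f.data(), d.data(), n, v.data(), z.data());
        for (int zz = 0; zz < nz; ++zz)
          D[(size_t)zz * nx * ny + (size_t)yy * nx + xx] = d[zz];
      }
  }
}

// Squared Euclidean distance to the nearest TRUE voxel of `target`.
// dims = (nx, ny, nz), x fastest (R column-major). slicewise = TRUE restricts
// the transform to 2D within each z-slice (circular-kernel semantics).
// Voxels in a slice/volume with no target voxel get a large finite value.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector target, IntegerVector dims,
                         bool slicewise) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t ntot = (size_t)nx * ny * nz;
  const double BIG = 1e18;
  std::vector<double> D(ntot);
  for (size_t i = 0; i < ntot; ++i) D[i] = target[i] ? 0.0 : BIG;
  pass_axis(D, nx, ny, nz, 0);
  pass_axis(D, nx, ny, nz, 1);
  if (!slicewise) pass_axis(D, nx, ny, nz, 2);
  NumericVector out(ntot);
  for (size_t i = 0; i < ntot; ++i) out[i] = std::min(D[i], BIG);
  out.attr("dim") = dims;
  return out;
}
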