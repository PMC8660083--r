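#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Volumes are stored as C x V matrices, V = nx*ny*nz, voxel index
// v = x + nx*(y + ny*z) (x fastest, matching R's column-major 3D arrays).

// Unfold a 3D multi-channel grid into the (C*k^3) x Vout matrix whose
// column j holds the receptive patch of output voxel j. Row layout is
// channel-fastest within each kernel offset:
//   row = c + C*(kx + k*(ky + k*kz)).
// Out-of-bounds (padding) samples are zero.
// [[Rcpp::export(name = ".im2col3d")]]
NumericMatrix im2col3d(const NumericMatrix& x, const IntegerVector& dims,
                       int k, int stride, int pad) {
  const int C = x.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = (nx + 2 * pad - k) / stride + 1;
  const int oy = (ny + 2 * pad - k) / stride + 1;
  const int oz = (nz + 2 * pad - k) / stride + 1;
  const int Vout = ox * oy * oz;
  NumericMatrix out(C * k * k * k, Vout);
  const double* xp = x.begin();
  double* op = out.begin();
  const int rows = C * k * k * k;
  for (int zo = 0; zo < oz; ++zo) {
    for (int yo = 0; yo < oy; ++yo) {
      for (int xo = 0; xo < ox; ++xo) {
        const int col = xo + ox * (yo + oy * zo);
        double* colp = op + (size_t)col * rows;
        for (int kz = 0; kz < k; ++kz) {
          const int zi = zo * stride - pad + kz;
          for (int ky = 0; ky < k; ++ky) {
            const int yi = yo * stride - pad + ky;
            for (int kx = 0; kx < k; ++kx) {
              const int xi = xo * stride - pad + kx;
              const int roff = C * (kx + k * (ky + k * kz));
              if (xi >= 0 && xi < nx && yi >= 0 && yi < ny &&
                  zi >= 0 && zi < nz) {
                const int v = xi + nx * (yi + ny * zi);
                const double* src = xp + (size_t)v * C;
                for (int c = 0; c < C; ++c) colp[roff + c] = src[c];
              }
              // else: leave zeros (padding)
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3d: scatter-add columns back onto the C x V input grid.
// Used for the gradient of a convolution with respect to its input.
// [[Rcpp::export(name = ".col2im3d")]]
NumericMatrix col2im3d(const NumericMatrix& cols, const IntegerVector& dims,
                       int C, int k, int stride, int pad) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = (nx + 2 * pad - k) / stride + 1;
  const int oy = (ny + 2 * pad - k) / stride + 1;
  const int oz = (nz + 2 * pad - k) / stride + 1;
  NumericMatrix out(C, nx * ny * nz);
  const int rows = C * k * k * k;
  if (cols.nrow() != rows) stop("column matrix has wrong row count");
  const double* cp = cols.begin();
  double* op = out.begin();
  for (int zo = 0; zo < oz; ++zo) {
    for (int yo = 0; yo < oy; ++yo) {
      for (int xo = 0; xo < ox; ++xo) {
        const int col = xo + ox * (yo + oy * zo);
        const double* colp = cp + (size_t)col * rows;
        for (int kz = 0; kz < k; ++kz) {
          const int zi = zo * stride - pad + kz;
          if (zi < 0 || zi >= nz) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int yi = yo * stride - pad + ky;
            if (yi < 0 || yi >= ny) continue;
            for (int kx = 0; kx < k; ++kx) {
              const int xi = xo * stride - pad + kx;
              if (xi < 0 || xi >= nx) continue;
              const int roff = C * (kx + k * (ky + k * kz));
              const int v = xi + nx * (yi + ny * zi);
              double* dst = op + (size_t)v * C;
              for (int c = 0; c < C; ++c) dst[c] += colp[roff + c];
            }
          }
        }
      }
    }
  }
  return out;
}

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double h) {
  // Lower-envelope distance transform of sampled function f on the grid
  // x_i = i*h (Felzenszwalb & Huttenlocher), squared distances.
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int kk = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * h;
    double s;
    while (true) {
      double xv = v[kk] * h;
      s = ((f[q] + xq * xq) - (f[v[kk]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q;
    z[kk] = s;
    z[kk + 1] = INF;
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[kk + 1] < xq) ++kk;
    double xv = v[kk] * h;
    d[q] = (xq - xv) * (xq - xv) + f[v[kk]];
  }
}

// Exact anisotropic Euclidean distance transform: for every voxel, the
// distance (in mm, voxel-center to voxel-center) to the nearest TRUE site.
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(const LogicalVector& sites, const IntegerVector& dims,
                    const NumericVector& spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t V = (size_t)nx * ny * nz;
  if ((size_t)sites.size() != V) stop("sites length does not match dims");
  // Large finite stand-in for +inf keeps the envelope arithmetic NaN-free
  // on rows that contain no site; it dominates any realizable distance.
  const double BIG = 1e30;
  std::vector<double> g(V);
  for (size_t i = 0; i < V; ++i) g[i] = sites[i] ? 0.0 : BIG;

  std::vector<double> f(std::max(nx, std::max(ny, nz)));
  std::vector<double> d(f.size());

  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      size_t base = (size_t)nx * (y + (size_t)ny * z);
      for (int x = 0; x < nx; ++x) f[x] = g[base + x];
      dt1d(f, d, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) g[base + x] = d[x];
    }
  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      size_t base = (size_t)x + (size_t)nx * ny * z;
      for (int y = 0; y < ny; ++y) f[y] = g[base + (size_t)nx * y];
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) g[base + (size_t)nx * y] = d[y];
    }
  // pass along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      size_t base = (size_t)x + (size_t)nx * y;
      for (int z = 0; z < nz; ++z) f[z] = g[base + (size_t)nx * ny * z];
      dt1d(f, d, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) g[base + (size_t)nx * ny * z] = d[z];
    }

  NumericVector out(V);
  for (size_t i = 0; i < V; ++i) out[i] = std::sqrt(g[i]);
  return out;
}
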