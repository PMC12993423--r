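#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Felzenszwalb & Huttenlocher lower-envelope distance transform, one line,
// with physical sample spacing s (positions x_i = i*s).
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double s) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    const double xq = q * s;
    double sx;
    while (true) {
      const double xv = v[k] * s;
      sx = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (sx <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = sx;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * s;
    while (z[k + 1] < xq) ++k;
    const double dx = xq - v[k] * s;
    d[q] = dx * dx + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest set voxel
// of a 3-D logical array, honouring anisotropic spacing.
// [[Rcpp::export]]
NumericVector edt_sq(LogicalVector mask, IntegerVector dims,
                     NumericVector spacing) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  // large finite sentinel: infinity breaks the lower-envelope intersections
  const double BIG = 1e30;
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(N);
  for (R_xlen_t i = 0; i < N; ++i) out[i] = mask[i] ? 0.0 : BIG;

  const int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (stride 1)
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      double* line = &out[(R_xlen_t)k * n1 * n2 + (R_xlen_t)j * n1];
      for (int i = 0; i < n1; ++i) f[i] = line[i];
      dt1d(f, d, v, z, n1, spacing[0]);
      for (int i = 0; i < n1; ++i) line[i] = d[i];
    }
  // axis 2 (stride n1)
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      double* base = &out[(R_xlen_t)k * n1 * n2 + i];
      for (int j = 0; j < n2; ++j) f[j] = base[(R_xlen_t)j * n1];
      dt1d(f, d, v, z, n2, spacing[1]);
      for (int j = 0; j < n2; ++j) base[(R_xlen_t)j * n1] = d[j];
    }
  // axis 3 (stride n1*n2)
  const R_xlen_t s3 = (R_xlen_t)n1 * n2;
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      double* base = &out[(R_xlen_t)j * n1 + i];
      for (int k = 0; k < n3; ++k) f[k] = base[k * s3];
      dt1d(f, d, v, z, n3, spacing[2]);
      for (int k = 0; k < n3; ++k) base[k * s3] = d[k];
    }
  return out;
}
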