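#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear interpolation of a 3-D volume (column-major, dims) at physical
// points (mm).  Continuous voxel index u = (p - origin)/spacing; points with
// any u outside [0, n-1] get NA.
// [[Rcpp::export]]
NumericVector trilinear(NumericVector vol, IntegerVector dims,
                        NumericVector origin, NumericVector spacing,
                        NumericMatrix pts) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t np = pts.nrow();
  NumericVector out(np);
  const double eps = 1e-9;
  for (R_xlen_t p = 0; p < np; ++p) {
    double u[3];
    bool ok = true;
    for (int a = 0; a < 3; ++a) {
      u[a] = (pts(p, a) - origin[a]) / spacing[a];
      const int n = dims[a];
      if (u[a] < -eps || u[a] > n - 1 + eps) { ok = false; break; }
      if (u[a] < 0) u[a] = 0;
      if (u[a] > n - 1) u[a] = n - 1;
    }
    if (!ok) { out[p] = NA_REAL; continue; }
    int i0 = std::min((int)std::floor(u[0]), n1 > 1 ? n1 - 2 : 0);
    int j0 = std::min((int)std::floor(u[1]), n2 > 1 ? n2 - 2 : 0);
    int k0 = std::min((int)std::floor(u[2]), n3 > 1 ? n3 - 2 : 0);
    const double fx = u[0] - i0, fy = u[1] - j0, fz = u[2] - k0;
    const int i1 = n1 > 1 ? i0 + 1 : i0;
    const int j1 = n2 > 1 ? j0 + 1 : j0;
    const int k1 = n3 > 1 ? k0 + 1 : k0;
    #define V(i, j, k) vol[(R_xlen_t)(k) * n1 * n2 + (R_xlen_t)(j) * n1 + (i)]
    const double c00 = V(i0, j0, k0) * (1 - fx) + V(i1, j0, k0) * fx;
    const double c10 = V(i0, j1, k0) * (1 - fx) + V(i1, j1, k0) * fx;
    const double c01 = V(i0, j0, k1) * (1 - fx) + V(i1, j0, k1) * fx;
    const double c11 = V(i0, j1, k1) * (1 - fx) + V(i1, j1, k1) * fx;
    #undef V
    const double c0 = c00 * (1 - fy) + c10 * fy;
    const double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Nearest-neighbour lookup, retained as the independent sampling mode for
// oracle comparisons.
// [[Rcpp::export]]
NumericVector nearest_sample(NumericVector vol, IntegerVector dims,
                             NumericVector origin, NumericVector spacing,
                             NumericMatrix pts) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t np = pts.nrow();
  NumericVector out(np);
  for (R_xlen_t p = 0; p < np; ++p) {
    int idx[3];
    bool ok = true;
    int nn[3] = {n1, n2, n3};
    for (int a = 0; a < 3; ++a) {
      const double u = (pts(p, a) - origin[a]) / spacing[a];
      const long i = (long)std::lround(u);
      if (i < 0 || i >= nn[a]) { ok = false; break; }
      idx[a] = (int)i;
    }
    out[p] = ok ? vol[(R_xlen_t)idx[2] * n1 * n2 + (R_xlen_t)idx[1] * n1 + idx[0]]
                : NA_REAL;
  }
  return out;
}
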