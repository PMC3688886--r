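#include <Rcpp.h>
using namespace Rcpp;

// Coordinates are 0-based voxel indices throughout; out-of-grid lookups
// clamp to the nearest edge voxel (the warping convention used everywhere).

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Trilinear interpolation of a 3-D array at arbitrary 0-based coordinates.
// [[Rcpp::export]]
NumericVector cpp_interp3(NumericVector vol, NumericVector xi,
                          NumericVector yi, NumericVector zi) {
  IntegerVector dim = vol.attr("dim");
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t m = xi.size();
  NumericVector out(m);
  const double* v = vol.begin();
  for (R_xlen_t i = 0; i < m; ++i) {
    double x = clampd(xi[i], 0.0, n1 - 1.0);
    double y = clampd(yi[i], 0.0, n2 - 1.0);
    double z = clampd(zi[i], 0.0, n3 - 1.0);
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 > n1 - 2) x0 = n1 - 2; if (x0 < 0) x0 = 0;
    if (y0 > n2 - 2) y0 = n2 - 2; if (y0 < 0) y0 = 0;
    if (z0 > n3 - 2) z0 = n3 - 2; if (z0 < 0) z0 = 0;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    if (n1 == 1) { x0 = 0; fx = 0.0; }
    if (n2 == 1) { y0 = 0; fy = 0.0; }
    if (n3 == 1) { z0 = 0; fz = 0.0; }
    const int x1 = (n1 == 1) ? 0 : x0 + 1;
    const int y1 = (n2 == 1) ? 0 : y0 + 1;
    const int z1 = (n3 == 1) ? 0 : z0 + 1;
    const R_xlen_t s2 = (R_xlen_t)n1, s3 = (R_xlen_t)n1 * n2;
    #define V(a,b,c) v[(a) + (b) * s2 + (c) * s3]
    double c00 = V(x0,y0,z0) * (1 - fx) + V(x1,y0,z0) * fx;
    double c10 = V(x0,y1,z0) * (1 - fx) + V(x1,y1,z0) * fx;
    double c01 = V(x0,y0,z1) * (1 - fx) + V(x1,y0,z1) * fx;
    double c11 = V(x0,y1,z1) * (1 - fx) + V(x1,y1,z1) * fx;
    #undef V
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[i] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Nearest-neighbour lookup of an integer-valued 3-D array.
// [[Rcpp::export]]
IntegerVector cpp_interp3_nn(IntegerVector vol, NumericVector xi,
                             NumericVector yi, NumericVector zi) {
  IntegerVector dim = vol.attr("dim");
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t m = xi.size();
  IntegerVector out(m);
  const int* v = vol.begin();
  const R_xlen_t s2 = (R_xlen_t)n1, s3 = (R_xlen_t)n1 * n2;
  for (R_xlen_t i = 0; i < m; ++i) {
    int x = (int)std::lround(clampd(xi[i], 0.0, n1 - 1.0));
    int y = (int)std::lround(clampd(yi[i], 0.0, n2 - 1.0));
    int z = (int)std::lround(clampd(zi[i], 0.0, n3 - 1.0));
    out[i] = v[x + y * s2 + z * s3];
  }
  return out;
}

// Sum over the clipped cube window of half-width r (separable passes).
// [[Rcpp::export]]
NumericVector cpp_boxsum3(NumericVector arr, int r) {
  IntegerVector dim = arr.attr("dim");
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  NumericVector cur = clone(arr);
  NumericVector nxt(cur.size());
  nxt.attr("dim") = dim;
  const R_xlen_t s2 = (R_xlen_t)n1, s3 = (R_xlen_t)n1 * n2;
  if (r <= 0) return cur;
  // pass along x
  for (int z = 0; z < n3; ++z)
    for (int y = 0; y < n2; ++y) {
      const double* in = cur.begin() + y * s2 + z * s3;
      double* outp = nxt.begin() + y * s2 + z * s3;
      double run = 0.0;
      int hi0 = std::min(r - 1, n1 - 1);
      for (int x = 0; x <= hi0; ++x) run += in[x];
      for (int x = 0; x < n1; ++x) {
        int hi = x + r, lo = x - r - 1;
        if (hi <= n1 - 1) run += in[hi];
        if (lo >= 0) run -= in[lo];
        outp[x] = run;
      }
    }
  std::swap(cur, nxt);
  // pass along y
  for (int z = 0; z < n3; ++z)
    for (int x = 0; x < n1; ++x) {
      const double* in = cur.begin() + x + z * s3;
      double* outp = nxt.begin() + x + z * s3;
      double run = 0.0;
      int hi0 = std::min(r - 1, n2 - 1);
      for (int y = 0; y <= hi0; ++y) run += in[y * s2];
      for (int y = 0; y < n2; ++y) {
        int hi = y + r, lo = y - r - 1;
        if (hi <= n2 - 1) run += in[hi * s2];
        if (lo >= 0) run -= in[lo * s2];
        outp[y * s2] = run;
      }
    }
  std::swap(cur, nxt);
  // pass along z
  for (int y = 0; y < n2; ++y)
    for (int x = 0; x < n1; ++x) {
      const double* in = cur.begin() + x + y * s2;
      double* outp = nxt.begin() + x + y * s2;
      double run = 0.0;
      int hi0 = std::min(r - 1, n3 - 1);
      for (int z = 0; z <= hi0; ++z) run += in[z * s3];
      for (int z = 0; z < n3; ++z) {
        int hi = z + r, lo = z - r - 1;
        if (hi <= n3 - 1) run += in[hi * s3];
        if (lo >= 0) run -= in[lo * s3];
        outp[z * s3] = run;
      }
    }
  return cur;
}

// Jacobian determinant of a coordinate map stored as an (n1,n2,n3,3) array of
// 0-based voxel coordinates; central differences inside, one-sided at faces.
// [[Rcpp::export]]
NumericVector cpp_jacdet3(NumericVector map) {
  IntegerVector dim = map.attr("dim");
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t s2 = (R_xlen_t)n1, s3 = (R_xlen_t)n1 * n2,
                 sc = (R_xlen_t)n1 * n2 * n3;
  NumericVector out((R_xlen_t)n1 * n2 * n3);
  out.attr("dim") = IntegerVector::create(n1, n2, n3);
  const double* m = map.begin();
  for (int z = 0; z < n3; ++z)
    for (int y = 0; y < n2; ++y)
      for (int x = 0; x < n1; ++x) {
        double J[3][3];
        for (int c = 0; c < 3; ++c) {
          const double* mc = m + c * sc;
          R_xlen_t idx = x + y * s2 + z * s3;
          // d/dx
          {
            int a = x > 0 ? x - 1 : x, b = x < n1 - 1 ? x + 1 : x;
            double h = (double)(b - a);
            J[c][0] = h > 0 ? (mc[b + y * s2 + z * s3] - mc[a + y * s2 + z * s3]) / h : 0.0;
          }
          // d/dy
          {
            int a = y > 0 ? y - 1 : y, b = y < n2 - 1 ? y + 1 : y;
            double h = (double)(b - a);
            J[c][1] = h > 0 ? (mc[x + b * s2 + z * s3] - mc[x + a * s2 + z * s3]) / h : 0.0;
          }
          // d/dz
          {
            int a = z > 0 ? z - 1 : z, b = z < n3 - 1 ? z + 1 : z;
            double h = (double)(b - a);
            J[c][2] = h > 0 ? (mc[x + y * s2 + b * s3] - mc[x + y * s2 + a * s3]) / h : 0.0;
          }
          (void)idx;
        }
        out[x + y * s2 + z * s3] =
          J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1]) -
          J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0]) +
          J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
      }
  return out;
}
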