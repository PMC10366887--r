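// Multi-energy non-local means on an axial slice stack.
// Stack layout: [Z, Y, X, E] column-major doubles.
// Patch distances share weights across energies: for output voxel i and
// candidate j, w_ij = exp(-sum_e d_e(i,j) / (2 h^2 sigma_e^2 |P|)) where
// d_e is the squared Euclidean distance between the cubic patches at energy e
// and |P| is the patch voxel count. Patches read from a mirror-padded copy
// (reflection about the edge voxel); the search window is clipped to the stack.

#include <Rcpp.h>
using namespace Rcpp;

static inline int mirror(int i, int n) {
  if (i < 0) i = -i;
  if (i >= n) i = 2 * n - 2 - i;
  return i;
}

// [[Rcpp::export]]
NumericVector menlm_stack_cpp(NumericVector stack, int out_z, int search_r,
                              int patch_r, double h, NumericVector sigma) {
  IntegerVector d = stack.attr("dim");
  const int Z = d[0], Y = d[1], X = d[2], E = d[3];
  const int z0 = out_z - 1;
  const int pn = (2 * patch_r + 1) * (2 * patch_r + 1) * (2 * patch_r + 1);

  // mirror-pad by patch_r in all three spatial dims
  const int Zp = Z + 2 * patch_r, Yp = Y + 2 * patch_r, Xp = X + 2 * patch_r;
  std::vector<double> P((size_t)Zp * Yp * Xp * E);
  for (int e = 0; e < E; ++e)
    for (int x = 0; x < Xp; ++x)
      for (int y = 0; y < Yp; ++y)
        for (int z = 0; z < Zp; ++z)
          P[(size_t)z + Zp * (y + (size_t)Yp * (x + (size_t)Xp * e))] =
              stack[mirror(z - patch_r, Z) +
                    Z * (mirror(y - patch_r, Y) +
                         (size_t)Y * (mirror(x - patch_r, X) + (size_t)X * e))];

  std::vector<double> invden(E);
  for (int e = 0; e < E; ++e) invden[e] = 1.0 / (2.0 * h * h * sigma[e] * sigma[e] * pn);

  NumericVector out((size_t)Y * X * E);
  out.attr("dim") = IntegerVector::create(Y, X, E);

  auto pat = [&](int z, int y, int x, int e) {
    return P[(size_t)(z + patch_r) +
             Zp * ((y + patch_r) + (size_t)Yp * ((x + patch_r) + (size_t)Xp * e))];
  };

  for (int x = 0; x < X; ++x) {
    for (int y = 0; y < Y; ++y) {
      double wsum = 0.0;
      std::vector<double> acc(E, 0.0);
      const int zlo = std::max(0, z0 - search_r), zhi = std::min(Z - 1, z0 + search_r);
      const int ylo = std::max(0, y - search_r), yhi = std::min(Y - 1, y + search_r);
      const int xlo = std::max(0, x - search_r), xhi = std::min(X - 1, x + search_r);
      for (int xj = xlo; xj <= xhi; ++xj)
        for (int yj = ylo; yj <= yhi; ++yj)
          for (int zj = zlo; zj <= zhi; ++zj) {
            double expo = 0.0;
            for (int e = 0; e < E; ++e) {
              double de = 0.0;
              for (int dx = -patch_r; dx <= patch_r; ++dx)
                for (int dy = -patch_r; dy <= patch_r; ++dy)
                  for (int dz = -patch_r; dz <= patch_r; ++dz) {
                    const double diff = pat(z0 + dz, y + dy, x + dx, e) -
                                        pat(zj + dz, yj + dy, xj + dx, e);
                    de += diff * diff;
                  }
              expo += de * invden[e];
            }
            const double w = std::exp(-expo);
            wsum += w;
            for (int e = 0; e < E; ++e)
              acc[e] += w * stack[zj + Z * (yj + (size_t)Y * (xj + (size_t)X * e))];
          }
      for (int e = 0; e < E; ++e)
        out[y + (size_t)Y * (x + (size_t)X * e)] = acc[e] / wsum;
    }
  }
  return out;
}
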