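#include <Rcpp.h>
using namespace Rcpp;

// Occupied-volume fraction of a union of spheres in a periodic box, by
// insertion on a regular grid of cell-center points.  Each atom only visits
// the grid points inside its own bounding window (a cell-list-equivalent
// linear-cost scheme); distances use the minimum-image convention and the
// identical floating-point expression as the brute-force oracle so results
// agree exactly.
// [[Rcpp::export]]
List occupied_grid_cpp(NumericMatrix centers, NumericVector radii,
                       NumericVector box, IntegerVector ngrid) {
  const int n = centers.nrow();
  const int n1 = ngrid[0], n2 = ngrid[1], n3 = ngrid[2];
  const double h1 = box[0] / n1, h2 = box[1] / n2, h3 = box[2] / n3;
  std::vector<char> occ((size_t)n1 * n2 * n3, 0);

  for (int ia = 0; ia < n; ++ia) {
    const double cx = centers(ia, 0), cy = centers(ia, 1), cz = centers(ia, 2);
    const double r = radii[ia], r2 = r * r;
    int i_lo = (int)std::floor((cx - r) / h1 - 0.5), i_hi = (int)std::ceil((cx + r) / h1 - 0.5);
    int j_lo = (int)std::floor((cy - r) / h2 - 0.5), j_hi = (int)std::ceil((cy + r) / h2 - 0.5);
    int k_lo = (int)std::floor((cz - r) / h3 - 0.5), k_hi = (int)std::ceil((cz + r) / h3 - 0.5);
    if (i_hi - i_lo + 1 > n1) { i_lo = 0; i_hi = n1 - 1; }
    if (j_hi - j_lo + 1 > n2) { j_lo = 0; j_hi = n2 - 1; }
    if (k_hi - k_lo + 1 > n3) { k_lo = 0; k_hi = n3 - 1; }
    for (int i = i_lo; i <= i_hi; ++i) {
      int im = ((i % n1) + n1) % n1;
      double dx = (im + 0.5) * h1 - cx;
      dx -= box[0] * std::nearbyint(dx / box[0]);
      for (int j = j_lo; j <= j_hi; ++j) {
        int jm = ((j % n2) + n2) % n2;
        double dy = (jm + 0.5) * h2 - cy;
        dy -= box[1] * std::nearbyint(dy / box[1]);
        for (int k = k_lo; k <= k_hi; ++k) {
          int km = ((k % n3) + n3) % n3;
          double dz = (km + 0.5) * h3 - cz;
          dz -= box[2] * std::nearbyint(dz / box[2]);
          if (dx * dx + dy * dy + dz * dz <= r2)
            occ[((size_t)im * n2 + jm) * n3 + km] = 1;
        }
      }
    }
  }
  long long cnt = 0;
  for (size_t q = 0; q < occ.size(); ++q) cnt += occ[q];
  return List::create(_["occupied"] = (double)cnt,
                      _["total"] = (double)((long long)n1 * n2 * n3));
}
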