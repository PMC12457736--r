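#include <Rcpp.h>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area.
//
// For every atom, a fixed set of quadrature points is placed on the sphere
// of radius (r_i + probe); a point is accessible when it lies outside the
// expanded sphere (r_j + probe) of every other atom.  The per-atom area is
// the accessible fraction of 4*pi*(r_i + probe)^2.  The point set is passed
// in from R (a deterministic golden-spiral lattice), so results are exactly
// reproducible for a given n_points.
//
// [[Rcpp::export]]
NumericVector sasa_cpp(NumericMatrix coords, NumericVector radii,
                       double probe, NumericMatrix sphere_points) {
  const int n = coords.nrow();
  const int m = sphere_points.nrow();
  NumericVector area(n);
  if (n == 0) return area;

  std::vector<double> x(n), y(n), z(n), re(n);
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) {
    x[i] = coords(i, 0); y[i] = coords(i, 1); z[i] = coords(i, 2);
    re[i] = radii[i] + probe;
    if (re[i] > rmax) rmax = re[i];
  }

  std::vector<int> nb; nb.reserve(64);
  std::vector<double> nbx, nby, nbz, nbr2;
  for (int i = 0; i < n; ++i) {
    nb.clear(); nbx.clear(); nby.clear(); nbz.clear(); nbr2.clear();
    const double cutoff = re[i] + rmax;
    const double cutoff2 = cutoff * cutoff;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
      const double d2 = dx * dx + dy * dy + dz * dz;
      const double touch = re[i] + re[j];
      if (d2 < touch * touch && d2 < cutoff2) {
        nbx.push_back(x[j]); nby.push_back(y[j]); nbz.push_back(z[j]);
        nbr2.push_back(re[j] * re[j]);
      }
    }
    const int nn = (int) nbx.size();
    int acc = 0;
    for (int k = 0; k < m; ++k) {
      const double px = x[i] + re[i] * sphere_points(k, 0);
      const double py = y[i] + re[i] * sphere_points(k, 1);
      const double pz = z[i] + re[i] * sphere_points(k, 2);
      bool free_pt = true;
      for (int j = 0; j < nn; ++j) {
        const double dx = px - nbx[j], dy = py - nby[j], dz = pz - nbz[j];
        if (dx * dx + dy * dy + dz * dz < nbr2[j]) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    area[i] = 4.0 * M_PI * re[i] * re[i] * ((double) acc / (double) m);
  }
  return area;
}
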