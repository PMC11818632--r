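#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Shrake-Rupley numerical SASA.
//
// Test points are placed on each atom's solvent-expanded sphere
// (radius_i + probe) with a deterministic golden-section spiral, so results
// are exactly reproducible for a fixed point count: no RNG is involved.
// A point survives if it lies outside every neighbour's expanded sphere;
// the atom's accessible area is the surviving fraction of 4*pi*(r+p)^2.

// [[Rcpp::export(name = ".sasa_atoms")]]
NumericVector sasa_atoms(NumericMatrix xyz, NumericVector radius,
                         double probe, int n_points) {
  const int n = xyz.nrow();
  if (radius.size() != n) stop("radius length must match atom count");
  if (probe <= 0) stop("probe radius must be positive");
  if (n_points < 60) stop("at least 60 sphere points required");

  // golden-section spiral on the unit sphere
  std::vector<double> ux(n_points), uy(n_points), uz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = golden * k;
    ux[k] = r * std::cos(phi);
    uy[k] = r * std::sin(phi);
    uz[k] = z;
  }

  NumericVector area(n);
  std::vector<int> nb;
  nb.reserve(64);

  for (int i = 0; i < n; ++i) {
    const double ri = radius[i] + probe;
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);

    // neighbours whose expanded spheres can clip atom i's test sphere
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double rj = radius[j] + probe;
      const double dx = xyz(j, 0) - xi, dy = xyz(j, 1) - yi,
                   dz = xyz(j, 2) - zi;
      const double d2 = dx * dx + dy * dy + dz * dz;
      const double rr = ri + rj;
      if (d2 < rr * rr) nb.push_back(j);
    }

    int accessible = 0;
    for (int k = 0; k < n_points; ++k) {
      const double px = xi + ri * ux[k];
      const double py = yi + ri * uy[k];
      const double pz = zi + ri * uz[k];
      bool free_point = true;
      for (size_t m = 0; m < nb.size(); ++m) {
        const int j = nb[m];
        const double rj = radius[j] + probe;
        const double dx = px - xyz(j, 0), dy = py - xyz(j, 1),
                     dz = pz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) {
          free_point = false;
          break;
        }
      }
      if (free_point) ++accessible;
    }
    area[i] = 4.0 * M_PI * ri * ri * accessible / n_points;
  }
  return area;
}

// Minimum heavy-atom distance from each atom of set A to any atom of set B.
// [[Rcpp::export(name = ".min_cross_dist")]]
NumericVector min_cross_dist(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      const double dx = a(i, 0) - b(j, 0), dy = a(i, 1) - b(j, 1),
                   dz = a(i, 2) - b(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
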