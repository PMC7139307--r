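#include <Rcpp.h>
using namespace Rcpp;

// Shrake-Rupley accessible surface area.
// coords: n x 3 (nm); radii: per-atom vdW radii (nm); probe: probe radius (nm);
// sphere: np x 3 unit vectors (deterministic Fibonacci point set, built in R).
// A quadrature point on atom i's probe-expanded sphere is exposed when it lies
// outside every neighbour's probe-expanded sphere.
// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix coords, NumericVector radii,
                       double probe, NumericMatrix sphere) {
  const int n = coords.nrow();
  const int np = sphere.nrow();
  NumericVector area(n);
  std::vector<double> ri(n);
  for (int i = 0; i < n; ++i) ri[i] = radii[i] + probe;

  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = coords(j, 0) - xi;
      const double dy = coords(j, 1) - yi;
      const double dz = coords(j, 2) - zi;
      const double lim = ri[i] + ri[j];
      if (dx * dx + dy * dy + dz * dz < lim * lim) nb.push_back(j);
    }
    int exposed = 0;
    for (int p = 0; p < np; ++p) {
      const double px = xi + ri[i] * sphere(p, 0);
      const double py = yi + ri[i] * sphere(p, 1);
      const double pz = zi + ri[i] * sphere(p, 2);
      bool occluded = false;
      for (size_t k = 0; k < nb.size(); ++k) {
        const int j = nb[k];
        const double dx = px - coords(j, 0);
        const double dy = py - coords(j, 1);
        const double dz = pz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < ri[j] * ri[j]) {
          occluded = true;
          break;
        }
      }
      if (!occluded) ++exposed;
    }
    area[i] = 4.0 * M_PI * ri[i] * ri[i] * (double)exposed / (double)np;
  }
  return area;
}

// Exact minimum cross-pair Euclidean distance between two atom index sets
// (1-based indices into coords rows).
// [[Rcpp::export]]
double cpp_min_cross_dist(NumericMatrix coords, IntegerVector ia,
                          IntegerVector ib) {
  double best = R_PosInf;
  for (int a = 0; a < ia.size(); ++a) {
    const int i = ia[a] - 1;
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    for (int b = 0; b < ib.size(); ++b) {
      const int j = ib[b] - 1;
      const double dx = coords(j, 0) - xi;
      const double dy = coords(j, 1) - yi;
      const double dz = coords(j, 2) - zi;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  }
  return std::sqrt(best);
}

// Number of cross pairs strictly closer than cutoff (nm).
// [[Rcpp::export]]
int cpp_count_close(NumericMatrix coords, IntegerVector ia, IntegerVector ib,
                    double cutoff) {
  const double c2 = cutoff * cutoff;
  int count = 0;
  for (int a = 0; a < ia.size(); ++a) {
    const int i = ia[a] - 1;
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    for (int b = 0; b < ib.size(); ++b) {
      const int j = ib[b] - 1;
      const double dx = coords(j, 0) - xi;
      const double dy = coords(j, 1) - yi;
      const double dz = coords(j, 2) - zi;
      if (dx * dx + dy * dy + dz * dz < c2) ++count;
    }
  }
  return count;
}
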