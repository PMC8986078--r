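#include <Rcpp.h>
using namespace Rcpp;

// Pairwise contact energy of cell i against all others at the given position.
// Neighbours are pairs closer than `reach`; each contributes the type-pair
// adhesion energy plus `beta` when either member is a perturbed beta cell.
static double local_energy(int i, double xi, double yi,
                           const NumericMatrix &pos, const IntegerVector &type,
                           const LogicalVector &pert, const NumericMatrix &J,
                           double beta, double reach2) {
  double e = 0.0;
  int n = pos.nrow();
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    double dx = pos(j, 0) - xi, dy = pos(j, 1) - yi;
    double d2 = dx * dx + dy * dy;
    if (d2 < reach2) {
      e += J(type[i], type[j]);
      if (pert[i] || pert[j]) e += beta;
    }
  }
  return e;
}

// Metropolis sweeps of single-cell Gaussian displacement moves for a
// differential-adhesion cell-sorting model on a circular domain.
// Uses R's RNG, so set.seed() on the R side makes runs bit-identical.
// The per-sweep total energy (each pair counted once) is returned as a
// trace for convergence diagnostics.
// [[Rcpp::export]]
List sorting_mc(NumericMatrix xy, IntegerVector type, LogicalVector perturbed,
                NumericMatrix J, double repulsion_beta, double domain_radius,
                double cell_radius, double temperature, int n_sweeps,
                double step_sd) {
  int n = xy.nrow();
  double reach = 2.5 * cell_radius;
  double reach2 = reach * reach;
  double rmax = domain_radius - cell_radius;
  double rmax2 = rmax * rmax;
  double mind2 = 4.0 * cell_radius * cell_radius;
  NumericMatrix pos = clone(xy);
  NumericVector energy_trace(n_sweeps);
  RNGScope scope;

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int i = 0; i < n; ++i) {
      double ox = pos(i, 0), oy = pos(i, 1);
      double nx = ox + norm_rand() * step_sd;
      double ny = oy + norm_rand() * step_sd;
      if (nx * nx + ny * ny > rmax2) continue;
      // single pass: overlap rejection + energy difference
      bool overlap = false;
      double de = 0.0;
      bool pi = perturbed[i];
      int ti = type[i];
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double px = pos(j, 0), py = pos(j, 1);
        double dxn = px - nx, dyn = py - ny;
        double d2n = dxn * dxn + dyn * dyn;
        if (d2n < mind2) { overlap = true; break; }
        double dxo = px - ox, dyo = py - oy;
        double d2o = dxo * dxo + dyo * dyo;
        bool in_new = d2n < reach2, in_old = d2o < reach2;
        if (in_new != in_old) {
          double eij = J(ti, type[j]);
          if (pi || perturbed[j]) eij += repulsion_beta;
          de += in_new ? eij : -eij;
        }
      }
      if (overlap) continue;
      if (de <= 0.0 || unif_rand() < std::exp(-de / temperature)) {
        pos(i, 0) = nx;
        pos(i, 1) = ny;
      }
    }
    double et = 0.0;
    for (int i = 0; i < n; ++i)
      et += local_energy(i, pos(i, 0), pos(i, 1), pos, type, perturbed, J,
                         repulsion_beta, reach2);
    energy_trace[sweep] = et / 2.0;
  }
  return List::create(_["xy"] = pos, _["energy"] = energy_trace);
}
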