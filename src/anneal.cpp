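#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Simulated annealing under a restraint set: harmonic backbone bonds,
// half-harmonic (upper-bound) contact restraints, soft spherical
// confinement and short-range excluded-volume repulsion
// (krep * (1 - d/drep)^2 for d < drep, tracked with a linked cell list).
// Temperatures are visited in the given order; proposals are
// single-particle Gaussian moves with the step scaled by sqrt(T).
// Indices are 0-based. Returns final coordinates plus the energy trace.
// [[Rcpp::export]]
List cpp_anneal(NumericMatrix xyz,
                IntegerVector bi, IntegerVector bj, NumericVector bt, double kb,
                IntegerVector ci, IntegerVector cj, NumericVector ct,
                NumericVector cw, double kc,
                double nuc_radius, double kconf,
                double drep, double krep,
                NumericVector temps, int sweeps_per_temp, double step) {
  const int n = xyz.nrow();
  NumericMatrix pos = clone(xyz);
  const int nb = bi.size(), nc = ci.size();

  // adjacency: per particle, indices of incident bond / contact restraints
  std::vector<std::vector<int>> badj(n), cadj(n);
  for (int r = 0; r < nb; ++r) {
    badj[bi[r]].push_back(r);
    badj[bj[r]].push_back(r);
  }
  for (int r = 0; r < nc; ++r) {
    cadj[ci[r]].push_back(r);
    cadj[cj[r]].push_back(r);
  }

  // linked cell list over a cube enclosing the nucleus (with slack for
  // transient excursions; particles outside are clamped to edge cells)
  const double box = nuc_radius * 2.0 + 8.0;
  const double origin = -box / 2.0;
  const double cell = std::max(drep, 1e-8);
  const int ncell = std::max(1, (int)std::floor(box / cell));
  const double cw_inv = ncell / box;
  auto cell_of = [&](double x, double y, double z) {
    int cx = (int)std::floor((x - origin) * cw_inv);
    int cy = (int)std::floor((y - origin) * cw_inv);
    int cz = (int)std::floor((z - origin) * cw_inv);
    cx = std::min(std::max(cx, 0), ncell - 1);
    cy = std::min(std::max(cy, 0), ncell - 1);
    cz = std::min(std::max(cz, 0), ncell - 1);
    return (cx * ncell + cy) * ncell + cz;
  };
  std::vector<std::vector<int>> cells(ncell * ncell * ncell);
  std::vector<int> cell_idx(n);
  for (int i = 0; i < n; ++i) {
    cell_idx[i] = cell_of(pos(i, 0), pos(i, 1), pos(i, 2));
    cells[cell_idx[i]].push_back(i);
  }
  auto rep_energy = [&](int i, double x, double y, double z) {
    if (krep <= 0.0) return 0.0;
    double e = 0.0;
    int cx = std::min(std::max((int)std::floor((x - origin) * cw_inv), 0),
                      ncell - 1);
    int cy = std::min(std::max((int)std::floor((y - origin) * cw_inv), 0),
                      ncell - 1);
    int cz = std::min(std::max((int)std::floor((z - origin) * cw_inv), 0),
                      ncell - 1);
    for (int ax = std::max(cx - 1, 0); ax <= std::min(cx + 1, ncell - 1); ++ax)
      for (int ay = std::max(cy - 1, 0); ay <= std::min(cy + 1, ncell - 1); ++ay)
        for (int az = std::max(cz - 1, 0); az <= std::min(cz + 1, ncell - 1); ++az)
          for (int o : cells[(ax * ncell + ay) * ncell + az]) {
            if (o == i) continue;
            double dx = x - pos(o, 0), dy = y - pos(o, 1), dz = z - pos(o, 2);
            double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 < drep * drep) {
              double d = std::sqrt(d2);
              double s = 1.0 - d / drep;
              e += krep * s * s;
            }
          }
    return e;
  };
  auto pair_dist = [&](int a, double x, double y, double z) {
    double dx = x - pos(a, 0), dy = y - pos(a, 1), dz = z - pos(a, 2);
    return std::sqrt(dx * dx + dy * dy + dz * dz);
  };
  auto particle_energy = [&](int i, double x, double y, double z) {
    double e = 0.0;
    for (int r : badj[i]) {
      int o = (bi[r] == i) ? bj[r] : bi[r];
      double d = pair_dist(o, x, y, z) - bt[r];
      e += kb * d * d;
    }
    for (int r : cadj[i]) {
      int o = (ci[r] == i) ? cj[r] : ci[r];
      double d = pair_dist(o, x, y, z);
      if (d > ct[r]) {
        double s = d - ct[r];
        e += kc * cw[r] * s * s;
      }
    }
    double rad = std::sqrt(x * x + y * y + z * z);
    if (rad > nuc_radius) {
      double s = rad - nuc_radius;
      e += kconf * s * s;
    }
    return e + rep_energy(i, x, y, z);
  };
  auto total_energy = [&]() {
    double e = 0.0;
    for (int r = 0; r < nb; ++r) {
      double dx = pos(bi[r], 0) - pos(bj[r], 0),
             dy = pos(bi[r], 1) - pos(bj[r], 1),
             dz = pos(bi[r], 2) - pos(bj[r], 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz) - bt[r];
      e += kb * d * d;
    }
    for (int r = 0; r < nc; ++r) {
      double dx = pos(ci[r], 0) - pos(cj[r], 0),
             dy = pos(ci[r], 1) - pos(cj[r], 1),
             dz = pos(ci[r], 2) - pos(cj[r], 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d > ct[r]) {
        double s = d - ct[r];
        e += kc * cw[r] * s * s;
      }
    }
    for (int i = 0; i < n; ++i) {
      double rad = std::sqrt(pos(i, 0) * pos(i, 0) + pos(i, 1) * pos(i, 1) +
                             pos(i, 2) * pos(i, 2));
      if (rad > nuc_radius) {
        double s = rad - nuc_radius;
        e += kconf * s * s;
      }
      e += 0.5 * rep_energy(i, pos(i, 0), pos(i, 1), pos(i, 2));
    }
    return e;
  };

  NumericVector trace(temps.size() + 1);
  trace[0] = total_energy();
  for (int t = 0; t < temps.size(); ++t) {
    double T = temps[t];
    double st = step * std::sqrt(T);
    for (int s = 0; s < sweeps_per_temp; ++s) {
      for (int k = 0; k < n; ++k) {
        int i = (int)(unif_rand() * n);
        if (i == n) i = n - 1;
        double nx = pos(i, 0) + st * norm_rand();
        double ny = pos(i, 1) + st * norm_rand();
        double nz = pos(i, 2) + st * norm_rand();
        double de = particle_energy(i, nx, ny, nz) -
                    particle_energy(i, pos(i, 0), pos(i, 1), pos(i, 2));
        if (de <= 0.0 || unif_rand() < std::exp(-de / T)) {
          pos(i, 0) = nx;
          pos(i, 1) = ny;
          pos(i, 2) = nz;
          int nc_idx = cell_of(nx, ny, nz);
          if (nc_idx != cell_idx[i]) {
            std::vector<int> &old = cells[cell_idx[i]];
            for (size_t q = 0; q < old.size(); ++q)
              if (old[q] == i) {
                old[q] = old.back();
                old.pop_back();
                break;
              }
            cells[nc_idx].push_back(i);
            cell_idx[i] = nc_idx;
          }
        }
      }
    }
    trace[t + 1] = total_energy();
    if (!R_finite(trace[t + 1]))
      stop("annealing diverged (non-finite energy) at temperature step %d",
           t + 1);
  }
  return List::create(_["coords"] = pos, _["energy"] = trace);
}
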