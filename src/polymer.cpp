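#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Metropolis relaxation of confined multi-chain polymers used by the
// synthetic-nucleus generator. One particle per (chromosome copy, bin);
// consecutive particles of the same chain are bonded.
//
// Energy terms (kT = 1):
//   bonds        kb * ((d - bond)/bond)^2, harmonic at all extensions
//   confinement  hard wall at the nuclear radius (moves outside rejected)
//   radial bias  -radial_coef * cpgz[i] * (r_i / nuc_radius)
//   territory    territory * |x_i - anchor(chain)|^2 / territory_r2
// where territory_r2 is the squared radius a single compact territory would
// occupy, so territory_strength ~ 1 already shapes distinct territories.
//
// radial_coef = radial_cpg_sign * radial_bias_strength, so positive values
// push CpG-rich particles outward ("inside-out") and negative values pull
// them toward the centre ("out-inside").
// [[Rcpp::export]]
NumericMatrix cpp_relax_chains(NumericMatrix xyz, IntegerVector chain,
                               NumericVector cpgz, NumericMatrix anchors,
                               double bond, double nuc_radius,
                               double radial_coef, double territory,
                               double territory_r2,
                               int sweeps, double step, double kb) {
  const int n = xyz.nrow();
  NumericMatrix pos = clone(xyz);
  const double r2max = nuc_radius * nuc_radius;

  auto bond_energy = [&](int i, double x, double y, double z) {
    double e = 0.0;
    for (int d = -1; d <= 1; d += 2) {
      int j = i + d;
      if (j < 0 || j >= n || chain[j] != chain[i]) continue;
      double dx = x - pos(j, 0), dy = y - pos(j, 1), dz = z - pos(j, 2);
      double dist = std::sqrt(dx * dx + dy * dy + dz * dz);
      double s = (dist - bond) / bond;
      e += kb * s * s;
    }
    return e;
  };
  auto field_energy = [&](int i, double x, double y, double z) {
    double r = std::sqrt(x * x + y * y + z * z);
    double e = -radial_coef * cpgz[i] * (r / nuc_radius);
    if (territory > 0) {
      int c = chain[i];
      double ax = x - anchors(c, 0), ay = y - anchors(c, 1),
             az = z - anchors(c, 2);
      e += territory * (ax * ax + ay * ay + az * az) / territory_r2;
    }
    return e;
  };

  for (int s = 0; s < sweeps; ++s) {
    for (int k = 0; k < n; ++k) {
      int i = (int)(unif_rand() * n);
      if (i == n) i = n - 1;
      double nx = pos(i, 0) + step * norm_rand();
      double ny = pos(i, 1) + step * norm_rand();
      double nz = pos(i, 2) + step * norm_rand();
      if (nx * nx + ny * ny + nz * nz > r2max) continue;  // hard wall
      double e_old = bond_energy(i, pos(i, 0), pos(i, 1), pos(i, 2)) +
                     field_energy(i, pos(i, 0), pos(i, 1), pos(i, 2));
      double e_new = bond_energy(i, nx, ny, nz) + field_energy(i, nx, ny, nz);
      double de = e_new - e_old;
      if (de <= 0.0 || unif_rand() < std::exp(-de)) {
        pos(i, 0) = nx;
        pos(i, 1) = ny;
        pos(i, 2) = nz;
      }
    }
  }
  return pos;
}

// All unordered particle pairs within `radius` (Euclidean). 0-based output.
// [[Rcpp::export]]
List cpp_neighbor_pairs(NumericMatrix xyz, double radius) {
  const int n = xyz.nrow();
  const double r2 = radius * radius;
  std::vector<int> ii, jj;
  std::vector<double> dd;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = xyz(i, 0) - xyz(j, 0);
      double dy = xyz(i, 1) - xyz(j, 1);
      double dz = xyz(i, 2) - xyz(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 <= r2) {
        ii.push_back(i);
        jj.push_back(j);
        dd.push_back(std::sqrt(d2));
      }
    }
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj), _["d"] = wrap(dd));
}
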