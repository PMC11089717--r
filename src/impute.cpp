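#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Haplotype codes: 0 = unknown, 1 = maternal, 2 = paternal.

static inline double l05(double dx, double dy) {
  double s = std::sqrt(std::fabs(dx)) + std::sqrt(std::fabs(dy));
  return s * s;
}

static inline long long pair_key(int a, int b) {
  int lo = a < b ? a : b, hi = a < b ? b : a;
  return (long long)lo * 1000000LL + hi;
}

// One synchronous round of neighbourhood voting. Targets keep their input
// order; evidence is never modified. Evidence contacts vote only with both
// haplotypes known; self-votes are excluded by contact id.
//
// Rules (all thresholds inclusive):
//  - intrachromosomal target with one known leg and separation <= s1:
//    assumed intrahomologous without voting;
//  - intrachromosomal target with both legs unknown: never imputed;
//  - a vote is cast iff the evidence contact lies within `w` in L^0.5
//    distance and matches exactly one enumerated haplotype tuple;
//  - the winning tuple needs >= v votes and >= f of all votes, no tie;
//  - an interhomologous win on an intrachromosomal target is accepted only
//    if the leg separation is >= s2.
// [[Rcpp::export]]
IntegerMatrix cpp_impute_round(IntegerVector t_chr_a, NumericVector t_pos_a,
                               IntegerVector t_hap_a, IntegerVector t_chr_b,
                               NumericVector t_pos_b, IntegerVector t_hap_b,
                               IntegerVector t_id,
                               IntegerVector e_chr_a, NumericVector e_pos_a,
                               IntegerVector e_hap_a, IntegerVector e_chr_b,
                               NumericVector e_pos_b, IntegerVector e_hap_b,
                               IntegerVector e_id,
                               double w, int v, double f, double s1, double s2) {
  const int nt = t_chr_a.size(), ne = e_chr_a.size();
  const double eps = 1e-9;
  IntegerMatrix out(nt, 2);

  // group usable (fully phased) evidence by unordered chromosome pair
  std::unordered_map<long long, std::vector<int>> groups;
  for (int e = 0; e < ne; ++e) {
    if (e_hap_a[e] == 0 || e_hap_b[e] == 0) continue;
    groups[pair_key(e_chr_a[e], e_chr_b[e])].push_back(e);
  }

  for (int t = 0; t < nt; ++t) {
    int ha = t_hap_a[t], hb = t_hap_b[t];
    out(t, 0) = ha;
    out(t, 1) = hb;
    if (ha != 0 && hb != 0) continue;  // fully phased, nothing to do
    const bool intra = (t_chr_a[t] == t_chr_b[t]);
    const double sep = std::fabs(t_pos_b[t] - t_pos_a[t]);

    if (intra) {
      if (ha == 0 && hb == 0) continue;  // never imputed in 2D
      if (sep <= s1 + eps) {             // intrahomologous shortcut
        int known = (ha != 0) ? ha : hb;
        out(t, 0) = known;
        out(t, 1) = known;
        continue;
      }
    }

    auto it = groups.find(pair_key(t_chr_a[t], t_chr_b[t]));
    if (it == groups.end()) continue;

    int counts[2][2] = {{0, 0}, {0, 0}};
    int total = 0;
    for (int e : it->second) {
      if (e_id[e] == t_id[t]) continue;  // no self-vote
      int ea, eb;
      double d;
      if (intra) {
        double d_dir = l05(e_pos_a[e] - t_pos_a[t], e_pos_b[e] - t_pos_b[t]);
        double d_swp = l05(e_pos_b[e] - t_pos_a[t], e_pos_a[e] - t_pos_b[t]);
        if (d_swp < d_dir) {
          d = d_swp;
          ea = e_hap_b[e];
          eb = e_hap_a[e];
        } else {
          d = d_dir;
          ea = e_hap_a[e];
          eb = e_hap_b[e];
        }
      } else {
        // canonical ordering makes leg chromosomes align, but stay defensive
        if (e_chr_a[e] == t_chr_a[t]) {
          d = l05(e_pos_a[e] - t_pos_a[t], e_pos_b[e] - t_pos_b[t]);
          ea = e_hap_a[e];
          eb = e_hap_b[e];
        } else {
          d = l05(e_pos_b[e] - t_pos_a[t], e_pos_a[e] - t_pos_b[t]);
          ea = e_hap_b[e];
          eb = e_hap_a[e];
        }
      }
      if (d > w + eps) continue;
      // compatible with exactly one enumerated tuple <=> matches known legs
      if (ha != 0 && ea != ha) continue;
      if (hb != 0 && eb != hb) continue;
      counts[ea - 1][eb - 1]++;
      total++;
    }
    if (total == 0) continue;
    int best = -1, besta = 0, bestb = 0;
    bool tie = false;
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b) {
        if (counts[a][b] > best) {
          best = counts[a][b];
          besta = a + 1;
          bestb = b + 1;
          tie = false;
        } else if (counts[a][b] == best && counts[a][b] > 0) {
          tie = true;
        }
      }
    if (tie || best < v) continue;
    if ((double)best + eps < f * (double)total) continue;
    if (intra && besta != bestb && sep + eps < s2) continue;  // interhomologous gate
    out(t, 0) = besta;
    out(t, 1) = bestb;
  }
  return out;
}

// Isolated-contact filter: a contact is kept iff at least `min_neighbors`
// other contacts on the same chromosome pair carry identical haplotypes on
// the matched legs within `w` in L^0.5 distance. Evaluated simultaneously on
// the input set. Contacts with unknown haplotypes can never match and are
// therefore always isolated.
// [[Rcpp::export]]
LogicalVector cpp_isolated_keep(IntegerVector chr_a, NumericVector pos_a,
                                IntegerVector hap_a, IntegerVector chr_b,
                                NumericVector pos_b, IntegerVector hap_b,
                                double w, int min_neighbors) {
  const int n = chr_a.size();
  const double eps = 1e-9;
  LogicalVector keep(n);
  std::unordered_map<long long, std::vector<int>> groups;
  for (int i = 0; i < n; ++i) groups[pair_key(chr_a[i], chr_b[i])].push_back(i);

  for (auto &kv : groups) {
    std::vector<int> &g = kv.second;
    std::vector<int> cnt(g.size(), 0);
    for (size_t a = 0; a < g.size(); ++a) {
      int i = g[a];
      if (hap_a[i] == 0 || hap_b[i] == 0) continue;
      for (size_t b = a + 1; b < g.size(); ++b) {
        int j = g[b];
        if (hap_a[j] == 0 || hap_b[j] == 0) continue;
        bool match;
        double d;
        if (chr_a[i] == chr_b[i]) {
          double d_dir = l05(pos_a[j] - pos_a[i], pos_b[j] - pos_b[i]);
          double d_swp = l05(pos_b[j] - pos_a[i], pos_a[j] - pos_b[i]);
          if (d_swp < d_dir) {
            d = d_swp;
            match = (hap_b[j] == hap_a[i] && hap_a[j] == hap_b[i]);
          } else {
            d = d_dir;
            match = (hap_a[j] == hap_a[i] && hap_b[j] == hap_b[i]);
          }
        } else {
          d = l05(pos_a[j] - pos_a[i], pos_b[j] - pos_b[i]);
          match = (hap_a[j] == hap_a[i] && hap_b[j] == hap_b[i]);
        }
        if (match && d <= w + eps) {
          cnt[a]++;
          cnt[b]++;
        }
      }
    }
    for (size_t a = 0; a < g.size(); ++a) keep[g[a]] = (cnt[a] >= min_neighbors);
  }
  return keep;
}
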