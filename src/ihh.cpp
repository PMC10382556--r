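#include <Rcpp.h>
using namespace Rcpp;

// One-sided integrated EHH walk from a core SNP outward.
// haplos: n x m binary matrix; pos: marker positions (bp); core: 1-based
// core index; step: +1 (right) or -1 (left). Returns NA when EHH never
// falls below ehh_min before the chromosome end, or when an inter-marker
// gap inside the integration span exceeds max_gap.
// [[Rcpp::export]]
double cpp_ihh_side(const IntegerMatrix& haplos, const NumericVector& pos,
                    int core, int step, double ehh_min, double max_gap) {
  const int n = haplos.nrow();
  const int m = haplos.ncol();
  const double denom = (double)n * (n - 1);
  std::vector<int> active(n), grp(n), newgrp(n);
  for (int i = 0; i < n; ++i) { active[i] = i; grp[i] = 0; }
  int n_active = n;
  double area = 0.0;
  double prev_pos = pos[core - 1], prev_e = 1.0;
  int j = core - 1;
  std::vector<int> first0, first1; // group id remap per (old group, allele)
  while (true) {
    j += step;
    if (j < 0 || j >= m) return NA_REAL;
    if (std::abs(pos[j] - prev_pos) > max_gap) return NA_REAL;
    // refine groups by allele at marker j
    first0.assign(n_active, -1);
    first1.assign(n_active, -1);
    int next_id = 0;
    for (int i = 0; i < n_active; ++i) {
      int a = haplos(active[i], j);
      int g = grp[i];
      int id;
      if (a == 0) {
        if (first0[g] < 0) first0[g] = next_id++;
        id = first0[g];
      } else {
        if (first1[g] < 0) first1[g] = next_id++;
        id = first1[g];
      }
      newgrp[i] = id;
    }
    // counts and singleton pruning
    std::vector<int> cnt(next_id, 0);
    for (int i = 0; i < n_active; ++i) cnt[newgrp[i]]++;
    double hom = 0.0;
    for (int g = 0; g < next_id; ++g)
      hom += (double)cnt[g] * (cnt[g] - 1);
    double e = hom / denom;
    int k = 0;
    std::vector<int> remap(next_id, -1);
    int next2 = 0;
    for (int i = 0; i < n_active; ++i) {
      if (cnt[newgrp[i]] > 1) {
        if (remap[newgrp[i]] < 0) remap[newgrp[i]] = next2++;
        active[k] = active[i];
        grp[k] = remap[newgrp[i]];
        ++k;
      }
    }
    n_active = k;
    area += std::abs(pos[j] - prev_pos) * (prev_e + e) / 2.0;
    prev_pos = pos[j];
    prev_e = e;
    if (e < ehh_min) return area;
  }
}
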