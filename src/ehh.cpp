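// EHH extension along an ordered site sequence with incremental haplotype
// class refinement. Haplotypes missing at any visited site drop out of the
// class count. Truncates one point past the cutoff crossing.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List ehh_extend_cpp(IntegerMatrix H, IntegerVector sites, NumericVector pos,
                    double cutoff, double max_extend) {
  const int n = H.nrow();
  const int ns = sites.size();
  std::vector<int> cls(n, 1), newcls(n);
  std::vector<bool> active(n, true);
  std::vector<double> dist;
  std::vector<double> val;
  dist.reserve(256); val.reserve(256);
  const double core_pos = pos[sites[0] - 1];
  dist.push_back(0.0);
  val.push_back(1.0);
  if (n < 2) return List::create(_["distance"] = dist, _["ehh"] = val);

  std::unordered_map<long long, int> remap;
  std::vector<int> counts;
  for (int k = 0; k < ns; ++k) {
    const int s = sites[k] - 1;
    const double d = std::fabs(pos[s] - core_pos);
    if (d > max_extend) break;
    remap.clear();
    int next_id = 0;
    int n_active = 0;
    for (int i = 0; i < n; ++i) {
      if (!active[i]) continue;
      int a = H(i, s);
      if (a == NA_INTEGER) { active[i] = false; continue; }
      long long key = 2LL * cls[i] + a;
      auto it = remap.find(key);
      int id;
      if (it == remap.end()) { id = next_id++; remap[key] = id; }
      else id = it->second;
      newcls[i] = id;
      ++n_active;
    }
    if (n_active < 2) break;
    counts.assign(next_id, 0);
    for (int i = 0; i < n; ++i) if (active[i]) { cls[i] = newcls[i]; ++counts[cls[i]]; }
    double num = 0.0;
    for (int c = 0; c < next_id; ++c)
      num += 0.5 * counts[c] * (counts[c] - 1.0);
    const double e = num / (0.5 * n_active * (n_active - 1.0));
    if (k > 0 || d > 0) { dist.push_back(d); val.push_back(e); }
    if (e < cutoff) break;
  }
  return List::create(_["distance"] = dist, _["ehh"] = val);
}
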