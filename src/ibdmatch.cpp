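// Exact/near-exact haplotype segment matching for one pair of haplotype
// rows: returns maximal runs containing at most `max_mismatch` discordant
// (or missing) sites, with runs trimmed to start and end on matches.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerMatrix match_runs_cpp(IntegerVector a, IntegerVector b, int max_mismatch) {
  const int S = a.size();
  std::vector<int> mm;  // positions (0-based) of mismatching sites
  mm.reserve(64);
  for (int j = 0; j < S; ++j) {
    if (a[j] == NA_INTEGER || b[j] == NA_INTEGER || a[j] != b[j]) mm.push_back(j);
  }
  std::vector<int> starts, ends;
  const int k = max_mismatch;
  const int nb = (int)mm.size();
  // bounds sentinel array: -1, mm..., S
  std::vector<int> bounds(nb + 2);
  bounds[0] = -1;
  for (int i = 0; i < nb; ++i) bounds[i + 1] = mm[i];
  bounds[nb + 1] = S;
  for (int i = 0; i + k + 1 < (int)bounds.size(); ++i) {
    int st = bounds[i] + 1;
    int en = bounds[i + k + 1] - 1;
    if (en < st) continue;
    // trim to matching endpoints
    int lo = st, hi = en;
    while (lo <= hi && (a[lo] == NA_INTEGER || b[lo] == NA_INTEGER || a[lo] != b[lo])) ++lo;
    while (hi >= lo && (a[hi] == NA_INTEGER || b[hi] == NA_INTEGER || a[hi] != b[hi])) --hi;
    if (hi >= lo) { starts.push_back(lo + 1); ends.push_back(hi + 1); }  // 1-based
  }
  // drop runs nested in the previous one (can arise after trimming)
  std::vector<int> ks, ke;
  for (size_t i = 0; i < starts.size(); ++i) {
    if (!ks.empty() && starts[i] >= ks.back() && ends[i] <= ke.back()) continue;
    ks.push_back(starts[i]); ke.push_back(ends[i]);
  }
  IntegerMatrix out(ks.size(), 2);
  for (size_t i = 0; i < ks.size(); ++i) { out(i, 0) = ks[i]; out(i, 1) = ke[i]; }
  return out;
}
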