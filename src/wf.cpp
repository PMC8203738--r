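// Wright-Fisher epoch kernel: per-generation multinomial reproduction with
// Poisson recombination, infinite-sites mutation (collision redraw against
// a genome-wide registry), optional genic selection at one tracked site,
// and an optional ancestry-marker matrix recombined with identical
// breakpoints. Uses R's RNG so runs are reproducible under set.seed().

#include <Rcpp.h>
#include <cstring>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export]]
List wf_epoch_cpp(IntegerMatrix H0, NumericVector pos0, IntegerVector N_traj,
                  double mu_total, double r_total, double L,
                  double s, double sweep_pos,
                  Nullable<IntegerMatrix> anc0, Nullable<NumericVector> marker_pos0,
                  RawVector used, int prune_every) {
  const int gens = N_traj.size();
  int N_cur = H0.nrow() / 2;
  int S = H0.ncol();

  int N_max = N_cur;
  for (int g = 0; g < gens; ++g) N_max = std::max(N_max, (int)N_traj[g]);
  const int rows_max = 2 * N_max;

  const int inj = (int)std::ceil(2.0 * N_max * mu_total) + 1;
  int cap = S + inj * (prune_every + 6) + 4096;

  std::vector<unsigned char> cur((size_t)rows_max * cap, 0),
                             nxt((size_t)rows_max * cap, 0);
  std::vector<double> pos(cap);
  for (int j = 0; j < S; ++j) pos[j] = pos0[j];
  for (int i = 0; i < 2 * N_cur; ++i)
    for (int j = 0; j < S; ++j)
      cur[(size_t)i * cap + j] = (unsigned char)H0(i, j);

  // ancestry markers (sorted positions)
  bool has_anc = anc0.isNotNull();
  int M = 0;
  std::vector<unsigned char> acur, anxt;
  std::vector<double> mpos;
  if (has_anc) {
    IntegerMatrix A(anc0);
    NumericVector mp(marker_pos0);
    M = A.ncol();
    mpos.assign(mp.begin(), mp.end());
    acur.assign((size_t)rows_max * M, 0);
    anxt.assign((size_t)rows_max * M, 0);
    for (int i = 0; i < 2 * N_cur; ++i)
      for (int j = 0; j < M; ++j)
        acur[(size_t)i * M + j] = (unsigned char)A(i, j);
  }

  std::vector<double> cumw(N_max);
  std::vector<double> bps(16);
  RNGScope scope;

  auto sweep_col = [&](void) -> int {
    if (sweep_pos < 0) return -1;
    for (int j = 0; j < S; ++j) if (pos[j] == sweep_pos) return j;
    return -1;
  };

  std::vector<int> colsum;
  auto prune = [&](void) {
    colsum.assign(S, 0);
    for (int i = 0; i < 2 * N_cur; ++i) {
      const unsigned char *row = &cur[(size_t)i * cap];
      for (int j = 0; j < S; ++j) colsum[j] += row[j];
    }
    std::vector<int> keep;
    keep.reserve(S);
    for (int j = 0; j < S; ++j) if (colsum[j] > 0) keep.push_back(j);
    if ((int)keep.size() == S) return;
    for (int i = 0; i < 2 * N_cur; ++i) {
      unsigned char *row = &cur[(size_t)i * cap];
      for (size_t k = 0; k < keep.size(); ++k) row[k] = row[keep[k]];
    }
    for (size_t k = 0; k < keep.size(); ++k) pos[k] = pos[keep[k]];
    S = (int)keep.size();
  };

  for (int g = 0; g < gens; ++g) {
    const int N_next = N_traj[g];
    const int sw = (s > 0) ? sweep_col() : -1;

    if (sw >= 0) {
      double acc = 0.0;
      for (int i = 0; i < N_cur; ++i) {
        int gt = cur[(size_t)(2 * i) * cap + sw] + cur[(size_t)(2 * i + 1) * cap + sw];
        double w = 1.0 + (gt == 2 ? s : (gt == 1 ? s / 2.0 : 0.0));
        acc += w;
        cumw[i] = acc;
      }
    }

    for (int k = 0; k < 2 * N_next; ++k) {
      int par;
      if (sw >= 0) {
        double u = unif_rand() * cumw[N_cur - 1];
        par = (int)(std::lower_bound(cumw.begin(), cumw.begin() + N_cur, u) -
                    cumw.begin());
        if (par >= N_cur) par = N_cur - 1;
      } else {
        par = (int)(unif_rand() * N_cur);
        if (par >= N_cur) par = N_cur - 1;
      }
      int h = (unif_rand() < 0.5) ? 0 : 1;
      const unsigned char *A = &cur[(size_t)(2 * par + h) * cap];
      const unsigned char *B = &cur[(size_t)(2 * par + 1 - h) * cap];
      unsigned char *child = &nxt[(size_t)k * cap];
      int ncx = (int)R::rpois(r_total);
      if (ncx == 0) {
        std::memcpy(child, A, S);
        if (has_anc)
          std::memcpy(&anxt[(size_t)k * M], &acur[(size_t)(2 * par + h) * M], M);
      } else {
        if ((int)bps.size() < ncx) bps.resize(ncx);
        for (int b = 0; b < ncx; ++b) bps[b] = unif_rand() * L;
        std::sort(bps.begin(), bps.begin() + ncx);
        if (ncx == 1) {          // the overwhelmingly common case
          const double b0 = bps[0];
          for (int j = 0; j < S; ++j)
            child[j] = (pos[j] < b0) ? A[j] : B[j];
        } else if (ncx == 2) {
          const double b0 = bps[0], b1 = bps[1];
          for (int j = 0; j < S; ++j)
            child[j] = (pos[j] < b0 || pos[j] >= b1) ? A[j] : B[j];
        } else {
          for (int j = 0; j < S; ++j) {
            int c = 0;
            for (int b = 0; b < ncx; ++b) if (bps[b] < pos[j]) ++c;
            child[j] = (c % 2 == 0) ? A[j] : B[j];
          }
        }
        if (has_anc) {
          const unsigned char *Am = &acur[(size_t)(2 * par + h) * M];
          const unsigned char *Bm = &acur[(size_t)(2 * par + 1 - h) * M];
          unsigned char *cm = &anxt[(size_t)k * M];
          for (int j = 0; j < M; ++j) {
            int c = 0;
            for (int b = 0; b < ncx; ++b) if (bps[b] < mpos[j]) ++c;
            cm[j] = (c % 2 == 0) ? Am[j] : Bm[j];
          }
        }
      }
    }
    std::swap(cur, nxt);
    if (has_anc) std::swap(acur, anxt);
    N_cur = N_next;

    // infinite-sites mutation in the new generation: batch the column
    // zeroing per row (contiguous writes) before setting carrier bits
    int nm = (int)R::rpois(2.0 * N_next * mu_total);
    if (nm > 0) {
      if (S + nm > cap) prune();
      if (S + nm > cap) nm = cap - S;  // capacity guard
      for (int i = 0; i < 2 * N_cur; ++i)
        std::memset(&cur[(size_t)i * cap + S], 0, nm);
      for (int m = 0; m < nm; ++m) {
        int ip;
        do {
          ip = (int)(unif_rand() * L);
          if (ip >= (int)L) ip = (int)L - 1;
        } while (used[ip] != 0);
        used[ip] = 1;
        int row = (int)(unif_rand() * 2 * N_cur);
        if (row >= 2 * N_cur) row = 2 * N_cur - 1;
        cur[(size_t)row * cap + S] = 1;
        pos[S] = ip + 1.0;  // 1-based bp
        ++S;
      }
    }

    if ((g + 1) % prune_every == 0 || S > cap - inj) prune();
  }
  prune();

  IntegerMatrix Hout(2 * N_cur, S);
  for (int i = 0; i < 2 * N_cur; ++i)
    for (int j = 0; j < S; ++j)
      Hout(i, j) = cur[(size_t)i * cap + j];
  NumericVector posout(S);
  for (int j = 0; j < S; ++j) posout[j] = pos[j];

  List out = List::create(_["H"] = Hout, _["pos"] = posout);
  if (has_anc) {
    IntegerMatrix Aout(2 * N_cur, M);
    for (int i = 0; i < 2 * N_cur; ++i)
      for (int j = 0; j < M; ++j)
        Aout(i, j) = acur[(size_t)i * M + j];
    out["anc"] = Aout;
  }
  return out;
}
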