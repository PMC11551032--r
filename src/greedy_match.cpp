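#include <Rcpp.h>
#include <algorithm>
#include <functional>
#include <vector>
using namespace Rcpp;

// Greedy variable-ratio caliper matching, pass-based:
// pass k = 1..max_ratio; treated processed in (descending score, position)
// order; controls live in (ascending score, position) order and each
// still-active treated unit takes its nearest available control within the
// caliper — on an exact distance tie, the lower-score (left) neighbour.
// A treated unit that finds no control is finished. Without replacement a
// control is used at most once globally; with replacement it may serve
// several treated units but appears at most once within one matched set.
// Positions are 1-based on input/output.

// [[Rcpp::export(name = ".greedy_match_cpp")]]
IntegerMatrix greedy_match_cpp(NumericVector scores, LogicalVector treated,
                               int max_ratio, double caliper,
                               bool with_replacement) {
  int n = scores.size();
  std::vector<int> t_idx, c_idx;
  for (int i = 0; i < n; ++i) (treated[i] ? t_idx : c_idx).push_back(i);
  int nt = t_idx.size(), m = c_idx.size();

  std::sort(t_idx.begin(), t_idx.end(), [&](int a, int b) {
    if (scores[a] != scores[b]) return scores[a] > scores[b];
    return a < b;
  });
  std::sort(c_idx.begin(), c_idx.end(), [&](int a, int b) {
    if (scores[a] != scores[b]) return scores[a] < scores[b];
    return a < b;
  });
  std::vector<double> sc(m);
  for (int j = 0; j < m; ++j) sc[j] = scores[c_idx[j]];

  // jump pointers over sorted control positions 0..m-1 (with -1 / m ends)
  std::vector<int> jl(m + 2), jr(m + 2);
  std::vector<char> avail(m, 1);
  // position p lives at index p+1: initial left jump p-1, right jump p+1
  for (int j = 0; j < m + 2; ++j) { jl[j] = j - 2; jr[j] = j; }
  // find_left(i): largest available j <= i, or -1 (i in [-1, m-1])
  std::function<int(int)> find_left = [&](int i) {
    int j = i;
    while (j >= 0 && !avail[j]) j = jl[j + 1];
    for (int k = i; k > j && k >= 0; ) { int nk = jl[k + 1]; jl[k + 1] = j; k = nk; }
    return j;
  };
  std::function<int(int)> find_right = [&](int i) {
    int j = i;
    while (j < m && !avail[j]) j = jr[j + 1];
    for (int k = i; k < j && k < m; ) { int nk = jr[k + 1]; jr[k + 1] = j; k = nk; }
    return j;
  };
  std::vector<char> active(nt, 1);
  std::vector<std::vector<int>> own(nt);
  std::vector<int> out_t, out_c, out_p;
  out_t.reserve(nt * max_ratio);

  for (int pass = 1; pass <= max_ratio; ++pass) {
    bool any_active = false;
    for (int ti = 0; ti < nt; ++ti) {
      if (!active[ti]) continue;
      double s = scores[t_idx[ti]];
      int pick = -1;
      // anchor: last sorted position with sc <= s
      int a = (int)(std::upper_bound(sc.begin(), sc.end(), s) - sc.begin()) - 1;
      if (with_replacement) {
        // per-set availability only: walk outward skipping this set's controls
        auto in_own = [&](int j) {
          for (int u : own[ti]) if (u == c_idx[j]) return true;
          return false;
        };
        int l = std::min(a, m - 1), r = a + 1;
        while (l >= 0 && in_own(l)) --l;
        while (r < m && in_own(r)) ++r;
        double dl = (l >= 0) ? s - sc[l] : R_PosInf;
        double dr = (r < m) ? sc[r] - s : R_PosInf;
        if (std::min(dl, dr) <= caliper) pick = c_idx[(dl <= dr) ? l : r];
      } else {
        int l = find_left(std::min(a, m - 1));
        int r = find_right(a + 1);
        double dl = (l >= 0) ? s - sc[l] : R_PosInf;
        double dr = (r < m) ? sc[r] - s : R_PosInf;
        if (std::min(dl, dr) <= caliper) {
          int ppos = (dl <= dr) ? l : r; // exact distance tie: left neighbour
          pick = c_idx[ppos];
          avail[ppos] = 0;
        }
      }
      if (pick < 0) { active[ti] = 0; continue; }
      any_active = true;
      own[ti].push_back(pick);
      out_t.push_back(t_idx[ti] + 1);
      out_c.push_back(pick + 1);
      out_p.push_back(pass);
    }
    if (!any_active) break;
  }

  IntegerMatrix out(out_t.size(), 3);
  for (size_t i = 0; i < out_t.size(); ++i) {
    out(i, 0) = out_t[i]; out(i, 1) = out_c[i]; out(i, 2) = out_p[i];
  }
  return out;
}
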