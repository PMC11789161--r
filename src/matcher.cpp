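// Correspondence search kernel for packing comparison.
//
// Depth-first search with forward checking over molecule-level candidate
// lists. Feasibility of a pair (i, j) against an assigned pair (k, jk):
//   |Ar(i,k) - Ap(j,jk)| <= angle_tol   (inter-centroid-vector angles, deg)
//   |Dr(i,k) - Dp(j,jk)| <= dist_tol * Dr(i,k)   (centroid distances)
// Candidate lists arrive pre-filtered by the per-molecule constraints
// (distance to central, species, orientation descriptors).
//
// The number of unmatched reference molecules is minimized by binary search
// on the skip budget: a complete traversal with <= s skips exists iff
// s >= s*, so the minimal feasible budget s* is found in O(log nr) runs and
// all maximal correspondences are enumerated at s* exactly. Within the DFS
// the next molecule to branch on is the one with the smallest remaining
// candidate list (fail-first), with molecules whose lists emptied consumed
// as forced skips first.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Search {
  const NumericMatrix &Ar, &Ap, &Dr, &Dp;
  double angle_tol, dist_tol;
  double budget;
  int keep;
  int nr, np;
  double trials = 0;
  bool limit_hit = false;
  bool feasible_found = false;   // stop-early mode: existence only
  bool existence_only = false;
  std::vector<int> assign;       // 0-based probe index or -1
  std::vector<char> used;
  std::vector<std::vector<int>> results;

  Search(const NumericMatrix &Ar_, const NumericMatrix &Ap_,
         const NumericMatrix &Dr_, const NumericMatrix &Dp_,
         double atol, double dtol, double budget_, int keep_, int np_)
      : Ar(Ar_), Ap(Ap_), Dr(Dr_), Dp(Dp_), angle_tol(atol), dist_tol(dtol),
        budget(budget_), keep(keep_), nr(Ar_.nrow()), np(np_),
        assign(Ar_.nrow(), -1), used(np_, 0) {}

  bool done() const {
    return limit_hit || (int)results.size() >= keep ||
           (existence_only && feasible_found);
  }

  std::vector<int> stamp;   // scratch for the union bound
  int stamp_id = 0;

  // Hall-type bound: the undecided molecules can match at most as many
  // distinct unused probe molecules as their domains jointly contain
  bool union_bound_fails(const std::vector<std::vector<int>> &dom,
                         int need) {
    if (need <= 0) return false;
    if ((int)stamp.size() != np) stamp.assign(np, 0);
    ++stamp_id;
    int distinct = 0;
    for (const auto &d : dom) {
      for (int j : d) {
        if (used[j] || stamp[j] == stamp_id) continue;
        stamp[j] = stamp_id;
        if (++distinct >= need) return false;
      }
    }
    return distinct < need;
  }

  // rows: indices of still-undecided reference molecules; dom: their
  // candidate lists (parallel to rows)
  void dfs(std::vector<int> rows, std::vector<std::vector<int>> dom,
           int skips_left) {
    if (done()) return;
    // consume molecules whose candidate lists are empty as forced skips
    for (size_t r = 0; r < rows.size();) {
      bool any = false;
      for (int j : dom[r])
        if (!used[j]) { any = true; break; }
      if (any) { ++r; continue; }
      if (skips_left == 0) return;   // infeasible under this budget
      --skips_left;
      rows.erase(rows.begin() + r);
      dom.erase(dom.begin() + r);
    }
    if (rows.empty()) {
      feasible_found = true;
      if (!existence_only) results.push_back(assign);
      return;
    }
    if (union_bound_fails(dom, (int)rows.size() - skips_left)) return;
    // fail-first: branch on the molecule with the fewest live candidates
    size_t pick = 0; int best_sz = -1;
    for (size_t r = 0; r < rows.size(); ++r) {
      int sz = 0;
      for (int j : dom[r])
        if (!used[j]) ++sz;
      if (best_sz < 0 || sz < best_sz) { best_sz = sz; pick = r; }
      if (sz == 1) { pick = r; break; }
    }
    int i = rows[pick];
    std::vector<int> my_dom = dom[pick];
    std::vector<int> sub_rows(rows);
    sub_rows.erase(sub_rows.begin() + pick);
    std::vector<std::vector<int>> sub_base(dom);
    sub_base.erase(sub_base.begin() + pick);

    for (int j : my_dom) {
      if (used[j]) continue;
      trials += 1;
      if (trials > budget) { limit_hit = true; return; }
      // propagate the (i, j) constraint to all undecided candidate lists
      std::vector<std::vector<int>> sub(sub_base);
      for (size_t r = 0; r < sub.size(); ++r) {
        int i2 = sub_rows[r];
        std::vector<int> v;
        v.reserve(sub[r].size());
        for (int j2 : sub[r]) {
          if (j2 == j) continue;
          if (std::abs(Ar(i2, i) - Ap(j2, j)) > angle_tol) continue;
          if (std::abs(Dr(i2, i) - Dp(j2, j)) > dist_tol * Dr(i2, i))
            continue;
          v.push_back(j2);
        }
        sub[r].swap(v);
      }
      assign[i] = j;
      used[j] = 1;
      dfs(sub_rows, sub, skips_left);
      assign[i] = -1;
      used[j] = 0;
      if (done()) return;
    }
    // leave molecule i unmatched even though candidates remain
    if (skips_left > 0) dfs(sub_rows, sub_base, skips_left - 1);
  }

  bool feasible(const std::vector<int> &rows,
                const std::vector<std::vector<int>> &dom, int s) {
    existence_only = true;
    feasible_found = false;
    std::fill(assign.begin(), assign.end(), -1);
    std::fill(used.begin(), used.end(), 0);
    dfs(rows, dom, s);
    existence_only = false;
    return feasible_found;
  }
};

}  // namespace

// [[Rcpp::export(name = ".match_clusters_cpp")]]
List match_clusters_cpp(NumericMatrix Ar, NumericMatrix Ap, NumericMatrix Dr,
                        NumericMatrix Dp, List cand, double angle_tol,
                        double dist_tol, double budget, int keep, int np,
                        int max_skips) {
  int nr = Ar.nrow();
  std::vector<std::vector<int>> dom(nr);
  std::vector<int> rows(nr);
  for (int i = 0; i < nr; ++i) {
    rows[i] = i;
    IntegerVector ci = cand[i];
    dom[i].assign(ci.begin(), ci.end());
    for (int &v : dom[i]) v -= 1;  // to 0-based
  }
  Search s(Ar, Ap, Dr, Dp, angle_tol, dist_tol, budget, keep, np);

  // binary search for the minimal feasible skip budget s*
  int lo = 0, hi = std::min(nr, max_skips);
  if (!s.feasible(rows, dom, hi)) {
    if (s.limit_hit)
      return List::create(_["limit"] = true, _["trials"] = s.trials);
    return List::create(_["limit"] = false,
                        _["assignments"] = List::create(),
                        _["trials"] = s.trials);
  }
  while (lo < hi) {
    int mid = lo + (hi - lo) / 2;
    bool ok = s.feasible(rows, dom, mid);
    if (s.limit_hit)
      return List::create(_["limit"] = true, _["trials"] = s.trials);
    if (ok) hi = mid; else lo = mid + 1;
  }

  // enumerate all maximal correspondences at the optimal budget
  s.results.clear();
  std::fill(s.assign.begin(), s.assign.end(), -1);
  std::fill(s.used.begin(), s.used.end(), 0);
  s.dfs(rows, dom, lo);
  if (s.limit_hit)
    return List::create(_["limit"] = true, _["trials"] = s.trials);

  List out(s.results.size());
  for (size_t r = 0; r < s.results.size(); ++r) {
    IntegerVector a(nr);
    for (int i = 0; i < nr; ++i)
      a[i] = s.results[r][i] < 0 ? NA_INTEGER : s.results[r][i] + 1;
    out[r] = a;
  }
  return List::create(_["limit"] = false, _["assignments"] = out,
                      _["trials"] = s.trials);
}
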