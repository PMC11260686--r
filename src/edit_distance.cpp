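#include <Rcpp.h>
#include <climits>
#include <cstdlib>
#include <string>
#include <vector>
using namespace Rcpp;

// Unit-cost Levenshtein distance between a and b.
// band >= 0 activates an Ukkonen band of half-width `band`: cells with
// |i - j| > band are treated as +inf. Any distance <= band is still exact;
// -1 is returned as soon as the true distance provably exceeds band.
// band < 0 computes the full (unbounded) DP.
static int lev_banded(const std::string& a, const std::string& b, long band) {
  const long n = (long)a.size(), m = (long)b.size();
  if (band >= 0 && std::labs(n - m) > band) return -1;
  if (n == 0) return (int)m;
  if (m == 0) return (int)n;
  const int INF = INT_MAX / 2;
  std::vector<int> prev((size_t)m + 1, INF), cur((size_t)m + 1, INF);
  long hi0 = (band >= 0) ? std::min(m, band) : m;
  for (long j = 0; j <= hi0; ++j) prev[(size_t)j] = (int)j;
  for (long i = 1; i <= n; ++i) {
    long lo = (band >= 0) ? std::max(1L, i - band) : 1L;
    long hi = (band >= 0) ? std::min(m, i + band) : m;
    std::fill(cur.begin(), cur.end(), INF);
    int rowmin = INF;
    if (lo == 1) { cur[0] = (int)i; rowmin = (int)i; }
    for (long j = lo; j <= hi; ++j) {
      int best = prev[(size_t)j - 1] + (a[(size_t)i - 1] != b[(size_t)j - 1]);
      if (prev[(size_t)j] + 1 < best) best = prev[(size_t)j] + 1;
      if (cur[(size_t)j - 1] + 1 < best) best = cur[(size_t)j - 1] + 1;
      cur[(size_t)j] = best;
      if (best < rowmin) rowmin = best;
    }
    if (band >= 0 && rowmin > band) return -1;
    std::swap(prev, cur);
  }
  int d = prev[(size_t)m];
  if (band >= 0 && d > band) return -1;
  return d;
}

// [[Rcpp::export(name = ".edit_distance_cpp")]]
int edit_distance_cpp(std::string a, std::string b, int band) {
  return lev_banded(a, b, band);
}

// All-nearest-neighbor search used by build_diwann().
//
// pivot (0-based) is the first sequence; its full distance row seeds both
// the triangle-inequality bound |d(p,i) - d(p,j)| <= d(i,j) and, for every
// other node, an initial current-best (its distance to the pivot). Each
// remaining pairwise distance is then either pruned by an admissible lower
// bound (length difference / triangle bound), abandoned early by the banded
// DP once it provably exceeds the current best, or computed exactly. The
// resulting edge set is provably identical to the full distance-matrix
// construction.
// [[Rcpp::export(name = ".diwann_core_cpp")]]
List diwann_core(std::vector<std::string> seqs, int pivot) {
  const int n = (int)seqs.size();
  if (n < 2) stop("need at least two sequences");
  if (pivot < 0 || pivot >= n) stop("pivot out of range");
  std::vector<long> len(n);
  for (int i = 0; i < n; ++i) len[i] = (long)seqs[i].size();

  long n_full = 0, n_pruned = 0, n_abandoned = 0;
  std::vector<int> d0(n, 0);
  for (int i = 0; i < n; ++i) {
    if (i == pivot) continue;
    d0[i] = lev_banded(seqs[pivot], seqs[i], -1);
    ++n_full;
  }

  std::vector<int> best(n, INT_MAX);
  std::vector<std::vector<int> > targets(n);

  // pivot row is already complete
  int bp = INT_MAX;
  for (int i = 0; i < n; ++i)
    if (i != pivot && d0[i] < bp) bp = d0[i];
  best[pivot] = bp;
  for (int i = 0; i < n; ++i)
    if (i != pivot && d0[i] == bp) targets[pivot].push_back(i);

  for (int i = 0; i < n; ++i) {
    if (i == pivot) continue;
    int bi = d0[i];
    std::vector<int> ti;
    ti.push_back(pivot);
    for (int j = 0; j < n; ++j) {
      if (j == i || j == pivot) continue;
      long lb = std::labs(len[i] - len[j]);
      long lb2 = std::labs((long)d0[i] - (long)d0[j]);
      if (lb2 > lb) lb = lb2;
      if (lb > bi) { ++n_pruned; continue; }
      int d = lev_banded(seqs[i], seqs[j], bi);
      if (d < 0) { ++n_abandoned; continue; }
      ++n_full;
      if (d < bi) {
        bi = d;
        ti.clear();
        ti.push_back(j);
      } else if (d == bi) {
        ti.push_back(j);
      }
    }
    best[i] = bi;
    targets[i] = ti;
  }

  // flatten edges (1-based indices), ordered by source then target
  std::vector<int> from, to, w;
  for (int i = 0; i < n; ++i) {
    std::vector<int> t = targets[i];
    std::sort(t.begin(), t.end());
    for (size_t k = 0; k < t.size(); ++k) {
      from.push_back(i + 1);
      to.push_back(t[k] + 1);
      w.push_back(best[i]);
    }
  }
  return List::create(
      _["from"] = wrap(from), _["to"] = wrap(to), _["weight"] = wrap(w),
      _["n_computed"] = (double)n_full, _["n_pruned"] = (double)n_pruned,
      _["n_abandoned"] = (double)n_abandoned);
}
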