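// Sequence kernels for the intrinsic metrics: token-level Levenshtein
// distance, longest common subsequence, and translation edit rate. TER uses
// an exact bounded-depth shift search when the hypothesis is short (shifts
// only permute the token multiset, so the state space stays small) and the
// standard greedy search beyond that: repeatedly apply the single span move
// that most reduces the remaining edit distance, each move costing one
// edit.

#include <Rcpp.h>
#include <map>
using namespace Rcpp;

static int lev(const std::vector<int>& a, const std::vector<int>& b) {
  size_t n = a.size(), m = b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (size_t j = 0; j <= m; ++j) prev[j] = (int)j;
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = (int)i;
    for (size_t j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      cur[j] = std::min({prev[j] + 1, cur[j - 1] + 1, sub});
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

static std::vector<int> to_vec(const IntegerVector& x) {
  return std::vector<int>(x.begin(), x.end());
}

// [[Rcpp::export]]
int cpp_lev(IntegerVector a, IntegerVector b) {
  auto va = to_vec(a), vb = to_vec(b);
  return lev(va, vb);
}

// [[Rcpp::export]]
int cpp_lcs(IntegerVector a, IntegerVector b) {
  size_t n = a.size(), m = b.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (size_t i = 1; i <= n; ++i) {
    for (size_t j = 1; j <= m; ++j) {
      cur[j] = (a[i - 1] == b[j - 1]) ? prev[j - 1] + 1
                                      : std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// move span [i, i+len) of h to start at position k (position in the sequence
// with the span removed)
static std::vector<int> apply_shift(const std::vector<int>& h, int i, int len,
                                    int k) {
  std::vector<int> rest;
  rest.reserve(h.size());
  for (int j = 0; j < (int)h.size(); ++j) {
    if (j < i || j >= i + len) rest.push_back(h[j]);
  }
  std::vector<int> out(rest.begin(), rest.begin() + k);
  for (int j = i; j < i + len; ++j) out.push_back(h[j]);
  out.insert(out.end(), rest.begin() + k, rest.end());
  return out;
}

// exact minimum of (#shifts + edit distance) by depth-first search over
// shift sequences with memoisation; tractable for short hypotheses because
// shifts only permute the token multiset
static void ter_exact_rec(const std::vector<int>& h, int nshift,
                          const std::vector<int>& r, int& best,
                          std::map<std::vector<int>, int>& seen) {
  if (nshift + 1 >= best) return;  // one more shift cannot improve
  int L = (int)h.size();
  for (int i = 0; i < L; ++i) {
    for (int len = 1; i + len <= L; ++len) {
      for (int k = 0; k <= L - len; ++k) {
        if (k == i) continue;
        std::vector<int> cand = apply_shift(h, i, len, k);
        if (cand == h) continue;
        auto it = seen.find(cand);
        if (it != seen.end() && it->second <= nshift + 1) continue;
        seen[cand] = nshift + 1;
        int tot = nshift + 1 + lev(cand, r);
        if (tot < best) best = tot;
        ter_exact_rec(cand, nshift + 1, r, best, seen);
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_ter(IntegerVector hyp, IntegerVector ref) {
  std::vector<int> h = to_vec(hyp), r = to_vec(ref);
  if (h.size() >= 2 && h.size() <= 8 && r.size() <= 10) {
    // exact shift search for short sequences
    int best = lev(h, r);
    std::map<std::vector<int>, int> seen;
    ter_exact_rec(h, 0, r, best, seen);
    return List::create(_["shifts"] = NA_INTEGER, _["edits"] = NA_INTEGER,
                        _["total"] = best);
  }
  int shifts = 0;
  int base = lev(h, r);
  while (base > 0 && h.size() > 1) {
    int best = base;
    std::vector<int> best_h;
    int L = (int)h.size();
    for (int i = 0; i < L; ++i) {
      for (int len = 1; i + len <= L; ++len) {
        for (int k = 0; k <= L - len; ++k) {
          if (k == i) continue;  // no-op move
          std::vector<int> cand = apply_shift(h, i, len, k);
          int d = lev(cand, r);
          if (d < best) {
            best = d;
            best_h = cand;
          }
        }
      }
    }
    if (best >= base) break;  // no shift reduces the remaining edit distance
    ++shifts;
    h = best_h;
    base = best;
  }
  return List::create(_["shifts"] = shifts, _["edits"] = base,
                      _["total"] = shifts + base);
}
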