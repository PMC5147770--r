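#include <Rcpp.h>
using namespace Rcpp;

// Base-pair maximization over nested structures with a minimum hairpin loop.
// Admissible pairs: A:U, G:C, G:U (T treated as U upstream).
// Traceback is deterministic: position i pairs the smallest admissible j
// consistent with an optimal structure, else stays unpaired.

static inline bool can_pair(char a, char b) {
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return true;
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return true;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return true;
  return false;
}

// [[Rcpp::export(name = ".nussinov_fold")]]
IntegerVector nussinov_fold(std::string seq, int min_loop) {
  int n = seq.size();
  IntegerVector partner(n, NA_INTEGER);
  if (n == 0) return partner;

  // DP over interval lengths; N[i][j] = max pairs in seq[i..j]
  std::vector<std::vector<short>> N(n, std::vector<short>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      short best = N[i + 1][j]; // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(seq[i], seq[k])) continue;
        short v = 1;
        if (k - 1 >= i + 1) v += N[i + 1][k - 1];
        if (k + 1 <= j) v += N[k + 1][j];
        if (v > best) best = v;
      }
      N[i][j] = best;
    }
  }

  // iterative traceback with explicit stack of intervals
  std::vector<std::pair<int, int>> stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i < min_loop + 1) continue;
    if (N[i][j] == 0) continue;
    bool paired = false;
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (!can_pair(seq[i], seq[k])) continue;
      short v = 1;
      if (k - 1 >= i + 1) v += N[i + 1][k - 1];
      if (k + 1 <= j) v += N[k + 1][j];
      if (v == N[i][j]) {
        partner[i] = k + 1; // 1-based for R; converted by caller
        partner[k] = i + 1;
        if (k - 1 > i) stack.push_back(std::make_pair(i + 1, k - 1));
        if (k + 1 < j) stack.push_back(std::make_pair(k + 1, j));
        paired = true;
        break;
      }
    }
    if (!paired) stack.push_back(std::make_pair(i + 1, j));
  }
  return partner;
}
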