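#include <Rcpp.h>
#include <vector>
#include <string>
#include <stack>
using namespace Rcpp;

// Nussinov-style maximum base-pair nested folding with a minimum hairpin
// loop. Pairs allowed: Watson-Crick (AU, GC) plus GU wobble when allow_gu.
// Deterministic traceback: at (i, j) pair i with the smallest partner k
// achieving the optimum; otherwise leave i unpaired.

static inline bool can_pair(char a, char b, bool allow_gu) {
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return true;
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return true;
  if (allow_gu && ((a == 'G' && b == 'U') || (a == 'U' && b == 'G'))) return true;
  return false;
}

// [[Rcpp::export(name = ".nussinov_cpp")]]
IntegerVector nussinov_cpp(std::string rna, int min_loop, bool allow_gu) {
  const int n = (int)rna.size();
  IntegerVector partner(n);
  for (int i = 0; i < n; ++i) partner[i] = 0;  // 0 = unpaired (1-based out)
  if (n < min_loop + 2) return partner;

  std::vector<std::vector<int> > N(n + 2, std::vector<int>(n + 2, 0));
  // N indices 1-based over [i, j]
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      int best = N[i + 1][j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(rna[i - 1], rna[k - 1], allow_gu)) continue;
        int v = 1 + N[i + 1][k - 1] + (k < j ? N[k + 1][j] : 0);
        if (v > best) best = v;
      }
      N[i][j] = best;
    }
  }

  std::stack<std::pair<int, int> > st;
  st.push(std::make_pair(1, n));
  while (!st.empty()) {
    int i = st.top().first, j = st.top().second;
    st.pop();
    if (i >= j || j - i < min_loop + 1) continue;
    int best = N[i][j];
    int chosen = -1;
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (!can_pair(rna[i - 1], rna[k - 1], allow_gu)) continue;
      int v = 1 + N[i + 1][k - 1] + (k < j ? N[k + 1][j] : 0);
      if (v == best) { chosen = k; break; }  // smallest k on ties
    }
    if (best == 0 || chosen < 0) {
      st.push(std::make_pair(i + 1, j));  // i unpaired
    } else {
      partner[i - 1] = chosen;
      partner[chosen - 1] = i;
      st.push(std::make_pair(i + 1, chosen - 1));
      if (chosen < j) st.push(std::make_pair(chosen + 1, j));
    }
  }
  return partner;
}
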