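#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Internal folding backend: Nussinov-style base-pair maximization with a
// minimum hairpin loop of 3 unpaired bases and an optional "must stay
// unpaired" mask. Energy is -(max number of nested canonical pairs), a toy
// unit that preserves the two properties the accessibility feature relies
// on: constrained >= unconstrained, and monotonicity in the mask.

namespace {

const int MIN_LOOP = 3;

inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'U': case 'T': return 3;
    default: return -1; // N or anything else: pairs with nothing
  }
}

inline bool can_pair(int a, int b) {
  if (a < 0 || b < 0) return false;
  return (a == 0 && b == 3) || (a == 3 && b == 0)   // AU
      || (a == 1 && b == 2) || (a == 2 && b == 1)   // GC
      || (a == 2 && b == 3) || (a == 3 && b == 2);  // GU wobble
}

} // namespace

// [[Rcpp::export(name = ".nussinov_pairs_cpp")]]
int nussinov_pairs_cpp(std::string seq, LogicalVector unpaired_mask) {
  int n = (int)seq.size();
  if (n == 0) return 0;
  if (unpaired_mask.size() != n) stop("mask length must equal segment length");
  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) {
    code[i] = base_code(seq[i]);
    if (unpaired_mask[i]) code[i] = -1; // forbidden to pair
  }
  // M[i][j]: max pairs in seq[i..j], stored flat
  std::vector<int> M((size_t)n * n, 0);
  auto at = [&](int i, int j) -> int& { return M[(size_t)i * n + j]; };
  for (int len = MIN_LOOP + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = at(i + 1, j); // i unpaired
      for (int l = i + MIN_LOOP + 1; l <= j; ++l) {
        if (!can_pair(code[i], code[l])) continue;
        int v = 1 + at(i + 1, l - 1) + (l < j ? at(l + 1, j) : 0);
        if (v > best) best = v;
      }
      at(i, j) = best;
    }
  }
  return at(0, n - 1);
}
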