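#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Match query window haplotypes against a window's library haplotypes.
//
// Haplotypes are strings over '0'/'1'; '9' marks a missing allele in a query
// (library haplotypes never contain missing). Mismatches are counted over the
// query's non-missing positions; a query qualifies against an entry when its
// mismatch count is at most floor(max_mismatch_fraction * n_informative).
// The unique entry at the minimal qualifying distance wins; two entries tied
// at the minimal distance, or no qualifying entry, give no match. A query
// with no informative position never matches.
//
// Returns the 1-based index of the matched library entry per query, 0 = none.
// [[Rcpp::export]]
IntegerVector match_windows_cpp(CharacterVector queries, CharacterVector lib,
                                double max_mismatch_fraction) {
  const int nq = queries.size(), nl = lib.size();
  IntegerVector out(nq);
  if (nl == 0) return out;
  for (int q = 0; q < nq; ++q) {
    const char *qs = CHAR(STRING_ELT(queries, q));
    const int L = (int) std::strlen(qs);
    int n_inf = 0;
    for (int i = 0; i < L; ++i) if (qs[i] != '9') ++n_inf;
    if (n_inf == 0) { out[q] = 0; continue; }
    const int max_mm = (int) std::floor(max_mismatch_fraction * n_inf + 1e-9);
    int best = -1, best_d = max_mm + 1;
    bool tie = false;
    for (int l = 0; l < nl; ++l) {
      const char *ls = CHAR(STRING_ELT(lib, l));
      int d = 0;
      const int limit = best_d;  // no point counting past the current best
      for (int i = 0; i < L; ++i) {
        if (qs[i] != '9' && qs[i] != ls[i]) {
          if (++d > limit) break;
        }
      }
      if (d > max_mm || d > best_d) continue;
      if (d < best_d) { best = l; best_d = d; tie = false; }
      else tie = true;  // d == best_d
    }
    out[q] = (best >= 0 && !tie) ? best + 1 : 0;
  }
  return out;
}
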