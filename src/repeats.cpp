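#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Best ungapped direct-repeat match between two sequence windows.
// Considers every equal-length substring pair (enumerated per diagonal)
// that starts and ends with a matching position (trimmed-alignment
// convention), has length >= min_len and mismatch fraction
// <= max_mismatch_frac. "Best" = most matching positions, ties broken
// by fewer mismatches, then by smaller start in a, then in b.
// Returns c(start_a, start_b, length, mismatches) 1-based, or all 0.

// [[Rcpp::export(name = ".best_repeat_cpp")]]
IntegerVector best_repeat_cpp(std::string a, std::string b, int min_len,
                              double max_mismatch_frac) {
  const int n = a.size(), m = b.size();
  int best_match = 0, best_mm = 0, best_i = 0, best_j = 0, best_len = 0;
  std::vector<int> pref;
  for (int d = -(n - 1); d < m; ++d) {
    const int i0 = d < 0 ? -d : 0;      // diagonal start in a
    const int j0 = d < 0 ? 0 : d;      // diagonal start in b
    const int len_d = std::min(n - i0, m - j0);
    if (len_d < min_len) continue;
    pref.assign(len_d + 1, 0);
    for (int k = 0; k < len_d; ++k)
      pref[k + 1] = pref[k] + (a[i0 + k] != b[j0 + k] ? 1 : 0);
    for (int s = 0; s < len_d; ++s) {
      if (len_d - s < std::max(best_match, min_len)) break;
      if (a[i0 + s] != b[j0 + s]) continue;  // anchor on a match
      for (int e = s + min_len; e <= len_d; ++e) {
        const int L = e - s;
        const int mm = pref[e] - pref[s];
        // even extending to the diagonal's end cannot reach tolerance
        if ((double)mm - max_mismatch_frac * L >
            max_mismatch_frac * (len_d - e))
          break;
        if (a[i0 + e - 1] != b[j0 + e - 1]) continue;  // end on a match
        if ((double)mm / L > max_mismatch_frac) continue;
        const int match = L - mm;
        const bool better =
            match > best_match ||
            (match == best_match &&
             (mm < best_mm ||
              (mm == best_mm &&
               (i0 + s < best_i ||
                (i0 + s == best_i && j0 + s < best_j)))));
        if (better) {
          best_match = match; best_mm = mm; best_len = L;
          best_i = i0 + s; best_j = j0 + s;
        }
      }
    }
  }
  if (best_len == 0) return IntegerVector::create(0, 0, 0, 0);
  return IntegerVector::create(best_i + 1, best_j + 1, best_len, best_mm);
}
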