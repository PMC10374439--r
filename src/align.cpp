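#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Pairwise end-free (overlap) alignment of each read against one reference,
// returning per read whether an insertion/deletion op overlaps the window
// [wstart, wend] in reference coordinates (1-based).  Substitutions never
// count as indels.  Reads whose best alignment score falls below
// min_frac * match * min(len_ref, len_read) are reported NA (unassignable).
//
// Gap placement near the window uses linear gap costs; traceback prefers the
// diagonal so mismatches are favored over gaps at equal score.
//
// Return codes: 1 = indel overlapping the window, 0 = no such indel,
// NA = alignment below the score floor.
// [[Rcpp::export(name = ".align_indel_window")]]
IntegerVector align_indel_window(CharacterVector reads, std::string ref,
                                 int wstart, int wend,
                                 int match = 2, int mismatch = -2,
                                 int gap = -5, double min_frac = 0.5) {
  const int m = ref.size();
  IntegerVector out(reads.size());
  std::vector<int> H((m + 1));
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    if (reads[r] == NA_STRING) { out[r] = NA_INTEGER; continue; }
    std::string read = as<std::string>(reads[r]);
    const int n = read.size();
    if (n == 0) { out[r] = NA_INTEGER; continue; }
    // score matrix (ref rows i, read cols j) + traceback
    std::vector<int> S((m + 1) * (n + 1));
    std::vector<unsigned char> T((m + 1) * (n + 1)); // 0 stop,1 diag,2 up(del),3 left(ins)
    for (int i = 0; i <= m; ++i) { S[i * (n + 1)] = 0; T[i * (n + 1)] = 0; }
    for (int j = 0; j <= n; ++j) { S[j] = 0; T[j] = 0; }
    for (int i = 1; i <= m; ++i) {
      const char rc = ref[i - 1];
      int *Si = &S[i * (n + 1)], *Sp = &S[(i - 1) * (n + 1)];
      unsigned char *Ti = &T[i * (n + 1)];
      for (int j = 1; j <= n; ++j) {
        int diag = Sp[j - 1] + (rc == read[j - 1] ? match : mismatch);
        int up = Sp[j] + gap;      // deletion: ref base i unmatched
        int left = Si[j - 1] + gap; // insertion: read base j unmatched
        int best = diag; unsigned char tb = 1;
        if (up > best) { best = up; tb = 2; }
        if (left > best) { best = left; tb = 3; }
        Si[j] = best; Ti[j] = tb;
      }
    }
    // best end point over last row / last column (free end gaps)
    int bi = m, bj = n, bscore = S[m * (n + 1) + n];
    for (int j = 0; j <= n; ++j)
      if (S[m * (n + 1) + j] > bscore) { bscore = S[m * (n + 1) + j]; bi = m; bj = j; }
    for (int i = 0; i <= m; ++i)
      if (S[i * (n + 1) + n] > bscore) { bscore = S[i * (n + 1) + n]; bi = i; bj = n; }
    int floor_len = m < n ? m : n;
    if (bscore < min_frac * match * floor_len) { out[r] = NA_INTEGER; continue; }
    // traceback collecting indel ops that touch the window
    bool hit = false;
    int i = bi, j = bj;
    while (i > 0 && j > 0) {
      unsigned char tb = T[i * (n + 1) + j];
      if (tb == 0) break;
      if (tb == 1) { --i; --j; }
      else if (tb == 2) { // deletion consumes ref base i
        if (i >= wstart && i <= wend) hit = true;
        --i;
      } else { // insertion after ref position i
        if (i >= wstart - 1 && i <= wend) hit = true;
        --j;
      }
    }
    out[r] = hit ? 1 : 0;
  }
  return out;
}
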