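#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Best ungapped overlap between a forward read's suffix and the
// reverse-complemented mate's prefix. Scans overlap lengths from the longest
// possible down to min_overlap; the accepted overlap minimises the mismatch
// fraction (ties to the longest overlap) subject to the fraction being at
// most max_mismatch_fraction. Returns a 2-column matrix (overlap,
// mismatches); overlap 0 marks an unmergeable pair.
//
// [[Rcpp::export]]
IntegerMatrix best_overlaps(CharacterVector fwd, CharacterVector rcrev,
                            int min_overlap, double max_mismatch_fraction) {
  const int n = fwd.size();
  IntegerMatrix out(n, 2);
  for (int p = 0; p < n; ++p) {
    const char *f = CHAR(STRING_ELT(fwd, p));
    const char *r = CHAR(STRING_ELT(rcrev, p));
    const int lf = LENGTH(STRING_ELT(fwd, p));
    const int lr = LENGTH(STRING_ELT(rcrev, p));
    int best_o = 0, best_m = 0;
    double best_frac = 2.0;
    for (int o = std::min(lf, lr); o >= min_overlap; --o) {
      int m = 0;
      const int cap = (int)(max_mismatch_fraction * o);
      const char *fs = f + lf - o;
      for (int i = 0; i < o; ++i) {
        if (fs[i] != r[i]) { if (++m > cap) break; }
      }
      double frac = (double)m / o;
      if (m <= cap && frac <= max_mismatch_fraction && frac < best_frac) {
        best_o = o; best_m = m; best_frac = frac;
        if (m == 0) break;  // unbeatable; ties go to the longest overlap
      }
    }
    out(p, 0) = best_o;
    out(p, 1) = best_m;
  }
  return out;
}

// Banded local alignment (Smith–Waterman with affine gaps) restricted to a
// band of half-width `band` around the diagonal `center` (offset = reference
// position − query position, 0-based). The band is anchored on the dominant
// shared-k-mer diagonal computed by the caller, the usual seed-and-extend
// shortcut for high-identity amplicon hits. Gap costs follow the BLAST
// convention: a gap of length L costs gap_open + L * gap_extend (both passed
// as negative numbers). Returns the best local score per (query, reference)
// pair; scores never go below 0.
//
// [[Rcpp::export]]
IntegerVector banded_local_scores(CharacterVector queries,
                                  CharacterVector refs,
                                  IntegerVector query_idx,
                                  IntegerVector ref_idx,
                                  IntegerVector center,
                                  int match, int mismatch,
                                  int gap_open, int gap_extend,
                                  int band) {
  const int npair = query_idx.size();
  IntegerVector out(npair);
  const int W = 2 * band + 1;
  const int NEG = -1000000000;
  std::vector<int> Mp(W), Xp(W), Yp(W), Mc(W), Xc(W), Yc(W);

  for (int p = 0; p < npair; ++p) {
    const char *q = CHAR(STRING_ELT(queries, query_idx[p] - 1));
    const char *s = CHAR(STRING_ELT(refs, ref_idx[p] - 1));
    const int n = LENGTH(STRING_ELT(queries, query_idx[p] - 1));
    const int m = LENGTH(STRING_ELT(refs, ref_idx[p] - 1));
    const int c = center[p];
    int best = 0;

    // row i = 0: only empty prefixes; all states start at 0 (local)
    for (int k = 0; k < W; ++k) { Mp[k] = 0; Xp[k] = NEG; Yp[k] = NEG; }

    for (int i = 1; i <= n; ++i) {
      for (int k = 0; k < W; ++k) { Mc[k] = NEG; Xc[k] = NEG; Yc[k] = NEG; }
      const int jlo = std::max(1, i + c - band);
      const int jhi = std::min(m, i + c + band);
      for (int j = jlo; j <= jhi; ++j) {
        const int k = j - (i + c) + band;           // band offset of (i, j)
        // diagonal predecessor (i-1, j-1) has the same band offset k
        int diag = std::max(Mp[k], std::max(Xp[k], Yp[k]));
        if (diag < 0) diag = 0;                      // local restart
        const int sub = (q[i - 1] == s[j - 1]) ? match : mismatch;
        int mval = diag + sub;
        if (mval < 0) mval = 0;
        Mc[k] = mval;
        // gap in reference (consume query base): predecessor (i-1, j), offset k+1
        if (k + 1 < W) {
          int open = (Mp[k + 1] > NEG / 2) ? Mp[k + 1] + gap_open + gap_extend : NEG;
          int ext  = (Xp[k + 1] > NEG / 2) ? Xp[k + 1] + gap_extend : NEG;
          Xc[k] = std::max(open, ext);
        }
        // gap in query (consume reference base): predecessor (i, j-1), offset k-1
        if (k - 1 >= 0) {
          int open = (Mc[k - 1] > NEG / 2) ? Mc[k - 1] + gap_open + gap_extend : NEG;
          int ext  = (Yc[k - 1] > NEG / 2) ? Yc[k - 1] + gap_extend : NEG;
          Yc[k] = std::max(open, ext);
        }
        if (Mc[k] > best) best = Mc[k];
      }
      std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
    }
    out[p] = best;
  }
  return out;
}
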