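#include <Rcpp.h>
using namespace Rcpp;

// IUPAC nucleotide codes as 4-bit masks over {A,C,G,T}.
static inline int iupac_mask(char c) {
  switch (c) {
  case 'A': return 1;
  case 'C': return 2;
  case 'G': return 4;
  case 'T': return 8;
  case 'R': return 1 | 4;          // A/G
  case 'Y': return 2 | 8;          // C/T
  case 'S': return 2 | 4;          // C/G
  case 'W': return 1 | 8;          // A/T
  case 'K': return 4 | 8;          // G/T
  case 'M': return 1 | 2;          // A/C
  case 'B': return 2 | 4 | 8;      // not A
  case 'D': return 1 | 4 | 8;      // not C
  case 'H': return 1 | 2 | 8;      // not G
  case 'V': return 1 | 2 | 4;      // not T
  case 'N': return 1 | 2 | 4 | 8;
  default:  return 0;
  }
}

// Hamming mismatches of a degenerate primer against one window of a read.
static inline int window_mismatches(const std::string &seq, size_t at,
                                    const std::vector<int> &pmask) {
  int mm = 0;
  for (size_t k = 0; k < pmask.size(); ++k) {
    int bm = iupac_mask(seq[at + k]);
    if ((pmask[k] & bm) == 0) ++mm;
  }
  return mm;
}

// Exhaustive scan of every window of `seq` for `primer` (IUPAC, 5'->3' as it
// would read on the scanned strand). Returns the window with the fewest
// mismatches <= max_mm; ties go to the leftmost window when leftmost=TRUE,
// otherwise to the rightmost. start is 0-based; returns start = -1 on no hit.
// [[Rcpp::export(name = ".scan_primer_cpp")]]
List scan_primer_cpp(std::string seq, std::string primer, int max_mm,
                     bool leftmost) {
  const size_t L = primer.size(), n = seq.size();
  if (n < L) return List::create(_["start"] = -1, _["mismatches"] = NA_INTEGER);
  std::vector<int> pmask(L);
  for (size_t k = 0; k < L; ++k) {
    int m = iupac_mask(primer[k]);
    if (m == 0) stop("invalid IUPAC code '%s' at primer position %d",
                     std::string(1, primer[k]), (int)(k + 1));
    pmask[k] = m;
  }
  int best = max_mm + 1;
  long best_at = -1;
  for (size_t i = 0; i + L <= n; ++i) {
    int mm = window_mismatches(seq, i, pmask);
    if (mm < best || (!leftmost && mm == best && best_at >= 0)) {
      best = mm;
      best_at = (long)i;
    }
  }
  if (best_at < 0 || best > max_mm)
    return List::create(_["start"] = -1, _["mismatches"] = NA_INTEGER);
  return List::create(_["start"] = (int)best_at, _["mismatches"] = best);
}

// Global alignment with free terminal gaps (match +1, mismatch -1, gap -2).
// Among maximum-score alignments the traceback maximises matched columns,
// then minimises aligned columns; terminal-gap columns are excluded from the
// column count. Returns score, matches, columns and identity =
// matches/columns (0 when the optimal alignment is empty).
// [[Rcpp::export(name = ".overlap_align_cpp")]]
List overlap_align_cpp(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  const int GAP = -2;
  // dp layers: score, matches, columns (columns negated for lexicographic max)
  std::vector<int> S((n + 1) * (m + 1)), M((n + 1) * (m + 1)),
      C((n + 1) * (m + 1));
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };
  for (int j = 0; j <= m; ++j) { S[idx(0, j)] = 0; M[idx(0, j)] = 0; C[idx(0, j)] = 0; }
  for (int i = 0; i <= n; ++i) { S[idx(i, 0)] = 0; M[idx(i, 0)] = 0; C[idx(i, 0)] = 0; }
  auto better = [](int s1, int m1, int c1, int s2, int m2, int c2) {
    if (s1 != s2) return s1 > s2;
    if (m1 != m2) return m1 > m2;
    return c1 < c2;
  };
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      bool eq = a[i - 1] == b[j - 1];
      int ds = S[idx(i - 1, j - 1)] + (eq ? 1 : -1);
      int dm = M[idx(i - 1, j - 1)] + (eq ? 1 : 0);
      int dc = C[idx(i - 1, j - 1)] + 1;
      int us = S[idx(i - 1, j)] + GAP, um = M[idx(i - 1, j)],
          uc = C[idx(i - 1, j)] + 1;
      int ls = S[idx(i, j - 1)] + GAP, lm = M[idx(i, j - 1)],
          lc = C[idx(i, j - 1)] + 1;
      int bs = ds, bm = dm, bc = dc;
      if (better(us, um, uc, bs, bm, bc)) { bs = us; bm = um; bc = uc; }
      if (better(ls, lm, lc, bs, bm, bc)) { bs = ls; bm = lm; bc = lc; }
      S[idx(i, j)] = bs; M[idx(i, j)] = bm; C[idx(i, j)] = bc;
    }
  }
  // free trailing gaps: best cell on last row or last column
  int bs = S[idx(n, m)], bm = M[idx(n, m)], bc = C[idx(n, m)];
  for (int j = 0; j <= m; ++j)
    if (better(S[idx(n, j)], M[idx(n, j)], C[idx(n, j)], bs, bm, bc)) {
      bs = S[idx(n, j)]; bm = M[idx(n, j)]; bc = C[idx(n, j)];
    }
  for (int i = 0; i <= n; ++i)
    if (better(S[idx(i, m)], M[idx(i, m)], C[idx(i, m)], bs, bm, bc)) {
      bs = S[idx(i, m)]; bm = M[idx(i, m)]; bc = C[idx(i, m)];
    }
  double ident = bc > 0 ? (double)bm / (double)bc : 0.0;
  return List::create(_["score"] = bs, _["matches"] = bm, _["columns"] = bc,
                      _["identity"] = ident);
}
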