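#include <Rcpp.h>
#include <cstring>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Hamming distance; strings must have equal length (checked by caller for vectors,
// re-checked here).
static int ham(const char* a, const char* b, int n) {
  int d = 0;
  for (int i = 0; i < n; ++i) d += (a[i] != b[i]);
  return d;
}

// Full Levenshtein distance, two-row DP.
static int lev(const char* a, int m, const char* b, int n) {
  std::vector<int> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = j;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    for (int j = 1; j <= n; ++j) {
      int sub = prev[j - 1] + (a[i - 1] != b[j - 1]);
      cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

// Semi-global DP: pattern aligned globally, text free at both ends.
// Fills row[j] = min edit distance of pattern vs text infix ending at position j
// (1-based; row[0] corresponds to the empty prefix).
static void infix_row(const char* p, int m, const char* t, int n, std::vector<int>& row) {
  std::vector<int> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = 0;   // free start in text
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;                                // gaps in text before pattern start
    for (int j = 1; j <= n; ++j) {
      int sub = prev[j - 1] + (p[i - 1] != t[j - 1]);
      cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
    }
    std::swap(prev, cur);
  }
  row = prev;
}

// [[Rcpp::export]]
IntegerVector hamming_cpp(CharacterVector a, CharacterVector b) {
  R_xlen_t na = a.size(), nb = b.size(), n = std::max(na, nb);
  if (na != nb && na != 1 && nb != 1)
    stop("arguments must have equal length (or length 1)");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* sa = CHAR(STRING_ELT(a, na == 1 ? 0 : i));
    const char* sb = CHAR(STRING_ELT(b, nb == 1 ? 0 : i));
    int la = (int) std::strlen(sa), lb = (int) std::strlen(sb);
    if (la != lb)
      stop("hamming distance requires equal-length strings (element %d: %d vs %d)",
           (int) i + 1, la, lb);
    out[i] = ham(sa, sb, la);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector levenshtein_cpp(CharacterVector a, CharacterVector b) {
  R_xlen_t na = a.size(), nb = b.size(), n = std::max(na, nb);
  if (na != nb && na != 1 && nb != 1)
    stop("arguments must have equal length (or length 1)");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* sa = CHAR(STRING_ELT(a, na == 1 ? 0 : i));
    const char* sb = CHAR(STRING_ELT(b, nb == 1 ? 0 : i));
    out[i] = lev(sa, (int) std::strlen(sa), sb, (int) std::strlen(sb));
  }
  return out;
}

// Fraction of bases with PHRED >= threshold, per quality string.
// [[Rcpp::export]]
LogicalVector qc_pass_cpp(CharacterVector qual, int phred_threshold,
                          double min_fraction, int offset = 33) {
  R_xlen_t n = qual.size();
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* q = CHAR(STRING_ELT(qual, i));
    int len = (int) std::strlen(q);
    if (len == 0) { out[i] = false; continue; }
    int pass = 0;
    for (int k = 0; k < len; ++k)
      if ((int) q[k] - offset >= phred_threshold) ++pass;
    out[i] = ((double) pass / (double) len) >= min_fraction;
  }
  return out;
}

// Minimum edit distance of `pattern` against any infix of `text`.
// [[Rcpp::export]]
int infix_edit_cpp(std::string pattern, std::string text) {
  int m = (int) pattern.size(), n = (int) text.size();
  std::vector<int> row;
  infix_row(pattern.c_str(), m, text.c_str(), n, row);
  int best = m;
  for (int j = 0; j <= n; ++j) best = std::min(best, row[j]);
  return best;
}

// Semi-global DP that also tracks, per end position, the minimum number of indels
// among the minimum-distance alignments (lexicographic (dist, indels) optimum).
// A substitution-only placement is preferred over an equal-distance placement that
// shifts the window with an indel.
static void infix_row2(const char* p, int m, const char* t, int n,
                       std::vector<int>& dist, std::vector<int>& indel) {
  std::vector<int> pd(n + 1), pi(n + 1), cd(n + 1), ci(n + 1);
  for (int j = 0; j <= n; ++j) { pd[j] = 0; pi[j] = 0; }
  for (int i = 1; i <= m; ++i) {
    cd[0] = i; ci[0] = i;  // pattern prefix unmatched: i deletions
    for (int j = 1; j <= n; ++j) {
      int d = pd[j - 1] + (p[i - 1] != t[j - 1]);  // sub/match
      int x = pi[j - 1];
      if (pd[j] + 1 < d || (pd[j] + 1 == d && pi[j] + 1 < x)) { d = pd[j] + 1; x = pi[j] + 1; }
      if (cd[j - 1] + 1 < d || (cd[j - 1] + 1 == d && ci[j - 1] + 1 < x)) { d = cd[j - 1] + 1; x = ci[j - 1] + 1; }
      cd[j] = d; ci[j] = x;
    }
    std::swap(pd, cd); std::swap(pi, ci);
  }
  dist = pd; indel = pi;
}

// Locate a 5' flank in each read: semi-global alignment of the flank, returning the
// 1-based text position where the best alignment ENDS. Among minimum-distance
// placements the one with fewest indels wins, then the LARGEST end (innermost:
// closest to the barcode). dist = -1 when the best distance exceeds max_dist.
// [[Rcpp::export]]
IntegerMatrix locate_flank5_cpp(std::string flank, CharacterVector reads, int max_dist) {
  R_xlen_t n = reads.size();
  IntegerMatrix out(n, 2);  // dist, end
  int m = (int) flank.size();
  std::vector<int> row, ind;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* t = CHAR(STRING_ELT(reads, i));
    int len = (int) std::strlen(t);
    infix_row2(flank.c_str(), m, t, len, row, ind);
    int best = m + 1, bestInd = m + 1, end = -1;
    for (int j = 0; j <= len; ++j)
      if (row[j] < best || (row[j] == best && ind[j] <= bestInd)) {
        best = row[j]; bestInd = ind[j]; end = j;        // <= keeps largest j
      }
    if (best > max_dist) { out(i, 0) = -1; out(i, 1) = -1; }
    else { out(i, 0) = best; out(i, 1) = end; }
  }
  return out;
}

// Locate a 3' flank: alignment computed on reversed strings so the returned value is the
// 1-based START position of the flank in the read; ties towards SMALLEST start
// (innermost).
// [[Rcpp::export]]
IntegerMatrix locate_flank3_cpp(std::string flank, CharacterVector reads, int max_dist) {
  R_xlen_t n = reads.size();
  IntegerMatrix out(n, 2);  // dist, start
  std::string rf(flank.rbegin(), flank.rend());
  int m = (int) rf.size();
  std::vector<int> row, ind;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* t = CHAR(STRING_ELT(reads, i));
    int len = (int) std::strlen(t);
    std::string rt(t, t + len);
    std::reverse(rt.begin(), rt.end());
    infix_row2(rf.c_str(), m, rt.c_str(), len, row, ind);
    int best = m + 1, bestInd = m + 1, endRev = -1;
    for (int j = 0; j <= len; ++j)
      if (row[j] < best || (row[j] == best && ind[j] <= bestInd)) {
        best = row[j]; bestInd = ind[j]; endRev = j;      // largest j in reversed space
      }
    if (best > max_dist) { out(i, 0) = -1; out(i, 1) = -1; }
    else { out(i, 0) = best; out(i, 1) = len - endRev + 1; }
  }
  return out;
}

// Tolerant reference matching with per-read candidate lists (1-based ref indices).
// For each read: minimum semi-global edit distance of each candidate reference against
// the read; report the reference achieving the unique minimum <= max_dist.
// Columns: ref (1-based, -1 = none), dist (-1 = none), ambiguous (0/1).
// [[Rcpp::export]]
IntegerMatrix best_reference_match_cpp(CharacterVector reads, CharacterVector refs,
                                       List candidates, int max_dist) {
  R_xlen_t n = reads.size();
  IntegerMatrix out(n, 3);
  R_xlen_t nref = refs.size();
  std::vector<const char*> rp(nref);
  std::vector<int> rl(nref);
  for (R_xlen_t k = 0; k < nref; ++k) {
    rp[k] = CHAR(STRING_ELT(refs, k));
    rl[k] = (int) std::strlen(rp[k]);
  }
  std::vector<int> row;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* t = CHAR(STRING_ELT(reads, i));
    int len = (int) std::strlen(t);
    IntegerVector cand = candidates[i];
    int best = max_dist + 1, bestRef = -1;
    bool tie = false;
    for (R_xlen_t c = 0; c < cand.size(); ++c) {
      int k = cand[c] - 1;
      int d;
      if (std::strstr(t, rp[k]) != NULL) {
        d = 0;
      } else if (best == 0) {
        continue;  // only another exact hit could tie a 0
      } else {
        infix_row(rp[k], rl[k], t, len, row);
        d = rl[k];
        for (int j = 0; j <= len; ++j) d = std::min(d, row[j]);
      }
      if (d < best) { best = d; bestRef = k + 1; tie = false; }
      else if (d == best && best <= max_dist && k + 1 != bestRef) tie = true;
    }
    if (bestRef == -1 || best > max_dist) { out(i, 0) = -1; out(i, 1) = -1; out(i, 2) = 0; }
    else if (tie) { out(i, 0) = -1; out(i, 1) = best; out(i, 2) = 1; }
    else { out(i, 0) = bestRef; out(i, 1) = best; out(i, 2) = 0; }
  }
  return out;
}
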