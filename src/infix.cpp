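#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Infix (semi-global) Levenshtein alignment of a short adapter/primer
// substring against a long read: the whole pattern must align, gaps on the
// read outside the matched interval are free.  Unit costs for substitution,
// insertion and deletion.  A base matches only itself and only if it is one
// of A/C/G/T, so N (in the read) and any masking symbol mismatch everything,
// including themselves.

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// Best alignment of `p` against any substring of t[lo, hi).
// Ties broken deterministically: minimal distance, then smallest start,
// then smallest end.  Returns false when the region is shorter than p.
static bool infix_region(const std::string& p, const std::string& t,
                         int lo, int hi, int& bd, int& bs, int& be) {
  const int n = (int) p.size();
  const int m = hi - lo;
  if (n < 1 || m < n) return false;

  // dp[j]: edit distance of p[0..i) vs the best-start substring of t ending
  // at lo + j; st[j]: the smallest such start among optimal alignments.
  std::vector<int> dp(m + 1), st(m + 1), dp2(m + 1), st2(m + 1);
  for (int j = 0; j <= m; ++j) { dp[j] = 0; st[j] = lo + j; }

  for (int i = 1; i <= n; ++i) {
    const char pc = p[i - 1];
    dp2[0] = i; st2[0] = lo;
    for (int j = 1; j <= m; ++j) {
      const char tc = t[lo + j - 1];
      const int cost = (pc == tc && is_acgt(pc)) ? 0 : 1;
      int v = dp[j - 1] + cost, s = st[j - 1];      // diagonal
      const int vu = dp[j] + 1;                     // gap in read
      if (vu < v || (vu == v && st[j] < s)) { v = vu; s = st[j]; }
      const int vl = dp2[j - 1] + 1;                // gap in pattern
      if (vl < v || (vl == v && st2[j - 1] < s)) { v = vl; s = st2[j - 1]; }
      dp2[j] = v; st2[j] = s;
    }
    dp.swap(dp2); st.swap(st2);
  }

  bool found = false;
  for (int j = 1; j <= m; ++j) {
    const int d = dp[j], s = st[j], e = lo + j;
    if (s >= e) continue;  // whole pattern deleted: not a real interval
    if (!found || d < bd || (d == bd && (s < bs || (s == bs && e < be)))) {
      found = true; bd = d; bs = s; be = e;
    }
  }
  return found;
}

static IntegerMatrix make_result(int nrow) {
  IntegerMatrix out(nrow, 3);
  std::fill(out.begin(), out.end(), NA_INTEGER);
  colnames(out) = CharacterVector::create("edit_distance", "read_start", "read_end");
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_infix_best(std::string pattern, CharacterVector texts) {
  const int nr = texts.size();
  IntegerMatrix out = make_result(nr);
  for (int i = 0; i < nr; ++i) {
    if (CharacterVector::is_na(texts[i])) continue;
    const std::string t = as<std::string>(texts[i]);
    int d, s, e;
    if (infix_region(pattern, t, 0, (int) t.size(), d, s, e)) {
      out(i, 0) = d; out(i, 1) = s; out(i, 2) = e;
    }
  }
  return out;
}

// Second-best alignment after excluding the interval [mstart, mend) of the
// first hit: the best alignment over the two flanking segments, so the
// result never overlaps the mask.  Coordinates stay on the original read.
// [[Rcpp::export]]
IntegerMatrix cpp_infix_second(std::string pattern, CharacterVector texts,
                               IntegerVector mstart, IntegerVector mend) {
  const int nr = texts.size();
  if (mstart.size() != nr || mend.size() != nr)
    stop("mask vectors must match the number of texts");
  IntegerMatrix out = make_result(nr);
  for (int i = 0; i < nr; ++i) {
    if (CharacterVector::is_na(texts[i])) continue;
    const std::string t = as<std::string>(texts[i]);
    const int len = (int) t.size();
    int ms = mstart[i], me = mend[i];
    if (ms == NA_INTEGER || me == NA_INTEGER) continue;
    if (ms < 0) ms = 0;
    if (me > len) me = len;
    int bd = -1, bs = -1, be = -1;
    int d, s, e;
    if (infix_region(pattern, t, 0, ms, d, s, e)) { bd = d; bs = s; be = e; }
    if (infix_region(pattern, t, me, len, d, s, e)) {
      if (bd < 0 || d < bd || (d == bd && (s < bs || (s == bs && e < be)))) {
        bd = d; bs = s; be = e;
      }
    }
    if (bd >= 0) { out(i, 0) = bd; out(i, 1) = bs; out(i, 2) = be; }
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  const int nr = x.size();
  CharacterVector out(nr);
  for (int i = 0; i < nr; ++i) {
    if (CharacterVector::is_na(x[i])) { out[i] = NA_STRING; continue; }
    std::string s = as<std::string>(x[i]);
    std::string r(s.rbegin(), s.rend());
    for (size_t j = 0; j < r.size(); ++j) {
      switch (r[j]) {
        case 'A': r[j] = 'T'; break;
        case 'C': r[j] = 'G'; break;
        case 'G': r[j] = 'C'; break;
        case 'T': r[j] = 'A'; break;
        case 'a': r[j] = 't'; break;
        case 'c': r[j] = 'g'; break;
        case 'g': r[j] = 'c'; break;
        case 't': r[j] = 'a'; break;
        default: break;  // N and anything else are self-complementary here
      }
    }
    out[i] = r;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_strrev(CharacterVector x) {
  const int nr = x.size();
  CharacterVector out(nr);
  for (int i = 0; i < nr; ++i) {
    if (CharacterVector::is_na(x[i])) { out[i] = NA_STRING; continue; }
    std::string s = as<std::string>(x[i]);
    out[i] = std::string(s.rbegin(), s.rend());
  }
  return out;
}
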