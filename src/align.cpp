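#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
#include <climits>

using namespace Rcpp;

// IUPAC nucleotide codes as 4-bit masks (A=1, C=2, G=4, T/U=8).
// Two positions match iff their code sets intersect.
static inline int iupacMask(char c) {
  switch (c) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'G': case 'g': return 4;
    case 'T': case 't': case 'U': case 'u': return 8;
    case 'R': case 'r': return 1 | 4;      // A/G
    case 'Y': case 'y': return 2 | 8;      // C/T
    case 'S': case 's': return 2 | 4;      // C/G
    case 'W': case 'w': return 1 | 8;      // A/T
    case 'K': case 'k': return 4 | 8;      // G/T
    case 'M': case 'm': return 1 | 2;      // A/C
    case 'B': case 'b': return 2 | 4 | 8;  // not A
    case 'D': case 'd': return 1 | 4 | 8;  // not C
    case 'H': case 'h': return 1 | 2 | 8;  // not G
    case 'V': case 'v': return 1 | 2 | 4;  // not T
    case 'N': case 'n': return 15;
    default: return 0;                     // gaps/invalid: caller strips these
  }
}

static void encodeSeq(const std::string& s, std::vector<int>& out) {
  out.clear();
  out.reserve(s.size());
  for (char c : s) {
    int m = iupacMask(c);
    if (m == 0) {
      if (c == '-' || c == '.') continue;  // gaps carry no information
      stop("invalid nucleotide character '%s' in sequence", std::string(1, c).c_str());
    }
    out.push_back(m);
  }
}

// End-gap-free ("overlap") global alignment by banded dynamic programming.
// Scoring: match +1, mismatch -1, gap -2 per gap column (open -2, each
// further column -2); terminal gaps are free. The band allows any offset
// implied by the length difference plus `slack` additional net indels on
// either side; alignments requiring more drift than that are treated as
// non-homologous (slack is generous relative to real COI barcodes, which
// are length-conserved).
//
// Among alignments with the optimal score, the one with the most matched
// columns (then the fewest aligned columns) is reported. That choice is
// deterministic and invariant under swapping the two sequences, which
// makes identity and p-distance exactly symmetric. Match and column
// counts cover the end-gap-free region only and are carried through the
// DP directly (no traceback needed).
struct AlignStats { int matches; int columns; int score; };

// Each DP cell holds the lexicographic objective (score, matches,
// -columns) packed into one int64 — 20 bits per field, score offset to
// stay non-negative — so the three-way preference reduces to a plain
// integer max and every DP move is a constant addition:
//   bits 40..: score + SOFF     (higher is better)
//   bits 20-39: matched columns (higher is better)
//   bits  0-19: CMAX - columns  (fewer columns is better)
static const int64_t SOFF = 1LL << 19;
static const int64_t CMAX = (1LL << 20) - 1;
static const int64_t START = (SOFF << 40) | CMAX;       // s=0, m=0, c=0
static const int64_t DEAD = -(1LL << 60);
static const int64_t D_MATCH = (1LL << 40) + (1LL << 20) - 1;  // +1 s, +1 m
static const int64_t D_MISS = -(1LL << 40) - 1;                // -1 s
static const int64_t D_GAP = -(2LL << 40) - 1;                 // -2 s

static AlignStats alignStats(const std::vector<int>& a, const std::vector<int>& b,
                             int slack) {
  const int la = (int)a.size(), lb = (int)b.size();
  AlignStats res = {0, 0, 0};
  if (la == 0 || lb == 0) return res;

  // band on the diagonal d = j - i
  int dmin = std::min(0, lb - la) - slack;
  int dmax = std::max(0, lb - la) + slack;

  // rows i = 0..la over a; banded columns stored at offset j - (i + dmin)
  const int width = dmax - dmin + 1;
  std::vector<int64_t> prev(width + 2, DEAD), cur(width + 2, DEAD);

  // row 0: leading gap in a is free
  for (int j = std::max(0, dmin); j <= std::min(lb, dmax); ++j)
    prev[j - dmin + 1] = START;

  int64_t best = DEAD;
  for (int i = 1; i <= la; ++i) {
    int jlo = std::max(0, i + dmin), jhi = std::min(lb, i + dmax);
    if (jlo > jhi) break;
    std::fill(cur.begin(), cur.end(), DEAD);
    const int ai = a[i - 1];
    const int off = i + dmin - 1;  // k = j - off
    int64_t* cu = cur.data();
    const int64_t* pr = prev.data();
    for (int j = jlo; j <= jhi; ++j) {
      int k = j - off;
      int64_t v;
      if (j == 0) {
        v = START;  // leading gap in b is free
      } else {
        // prev row is offset by one diagonal: prev index for (i-1, j-1)
        // is k, for (i-1, j) is k+1
        v = pr[k] + ((ai & b[j - 1]) ? D_MATCH : D_MISS);
        int64_t up = pr[k + 1] + D_GAP;
        if (up > v) v = up;
        int64_t left = cu[k - 1] + D_GAP;
        if (left > v) v = left;
      }
      cu[k] = v;
      if ((i == la || j == lb) && v > best) best = v;
    }
    std::swap(prev, cur);
  }

  if (best <= DEAD / 2) return res;  // no in-band path
  res.columns = (int)(CMAX - (best & CMAX));
  res.matches = (int)((best >> 20) & CMAX);
  res.score = (int)((best >> 40) - SOFF);
  return res;
}

// [[Rcpp::export(name = ".cppAlignStats")]]
IntegerVector cppAlignStats(std::string a, std::string b, int slack = 50) {
  std::vector<int> ea, eb;
  encodeSeq(a, ea);
  encodeSeq(b, eb);
  AlignStats s = alignStats(ea, eb, slack);
  return IntegerVector::create(Named("matches") = s.matches,
                               Named("columns") = s.columns,
                               Named("score") = s.score);
}

// Identity of one query against many references.
// [[Rcpp::export(name = ".cppIdentityBatch")]]
IntegerMatrix cppIdentityBatch(std::string query, CharacterVector refs,
                               int slack = 50) {
  std::vector<int> eq, er;
  encodeSeq(query, eq);
  const int n = refs.size();
  IntegerMatrix out(n, 2);
  colnames(out) = CharacterVector::create("matches", "columns");
  for (int r = 0; r < n; ++r) {
    encodeSeq(as<std::string>(refs[r]), er);
    AlignStats s = alignStats(eq, er, slack);
    out(r, 0) = s.matches;
    out(r, 1) = s.columns;
  }
  return out;
}

// Full query x reference match/column count matrices.
// [[Rcpp::export(name = ".cppIdentityMatrix")]]
List cppIdentityMatrix(CharacterVector queries, CharacterVector refs,
                       int slack = 50) {
  const int nq = queries.size(), nr = refs.size();
  IntegerMatrix matches(nq, nr), columns(nq, nr);
  std::vector<std::vector<int> > er(nr);
  for (int r = 0; r < nr; ++r) encodeSeq(as<std::string>(refs[r]), er[r]);
  std::vector<int> eq;
  for (int q = 0; q < nq; ++q) {
    encodeSeq(as<std::string>(queries[q]), eq);
    for (int r = 0; r < nr; ++r) {
      AlignStats s = alignStats(eq, er[r], slack);
      matches(q, r) = s.matches;
      columns(q, r) = s.columns;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(Named("matches") = matches, Named("columns") = columns);
}

// Symmetric all-vs-all match/column counts (upper triangle computed once).
// [[Rcpp::export(name = ".cppPairwiseStats")]]
List cppPairwiseStats(CharacterVector seqs, int slack = 50) {
  const int n = seqs.size();
  IntegerMatrix matches(n, n), columns(n, n);
  std::vector<std::vector<int> > es(n);
  for (int i = 0; i < n; ++i) encodeSeq(as<std::string>(seqs[i]), es[i]);
  for (int i = 0; i < n; ++i) {
    matches(i, i) = columns(i, i) = (int)es[i].size();
    for (int j = i + 1; j < n; ++j) {
      AlignStats s = alignStats(es[i], es[j], slack);
      matches(i, j) = matches(j, i) = s.matches;
      columns(i, j) = columns(j, i) = s.columns;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(Named("matches") = matches, Named("columns") = columns);
}
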