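#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Global pairwise alignment with affine gaps. Scoring: match +1,
// mismatch -1; every gap of length k, terminal or internal, costs
// open + (k-1)*ext (defaults open 2, ext 1). Identity = matching columns /
// alignment columns, where terminal gap runs are excluded from the
// columns (mapping semantics: a short amplicon aligned inside a
// full-length reference is scored on its aligned core). Penalizing
// terminal gaps in the score prevents the degenerate short suffix/prefix
// overlaps that would otherwise give unrelated sequences perfect
// identities.
//
// Among equal-scoring alignments the canonical one maximizes matching
// columns and then minimizes alignment columns, a purely value-based
// choice that makes the reported identity symmetric in the two
// sequences. The same convention is documented for (and required of)
// any oracle.

static const int NEG = -100000000;  // never approached: decrements are bounded

struct Cell {
  int score;
  int match;
  int cols;
};

static inline void enc(const std::string& s, std::vector<int>& v) {
  v.resize(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (int) s[i];
}

struct Tri { int s; int m; int c; };

static inline bool tri_better(const Tri& a, const Tri& b) {
  if (a.s != b.s) return a.s > b.s;
  if (a.m != b.m) return a.m > b.m;
  return a.c < b.c;
}

static inline int gap_run(int k, int gap_open, int gap_ext) {
  return k <= 0 ? 0 : gap_open + (k - 1) * gap_ext;
}

static void align_pair(const std::vector<int>& a, const std::vector<int>& b,
                       int match_s, int mismatch_s, int gap_open, int gap_ext,
                       Cell& out) {
  const int n = (int) a.size(), m = (int) b.size();
  if (n == 0 || m == 0) { out = {0, 0, 0}; return; }
  const Tri none = {NEG, 0, 0};
  std::vector<Tri> Mp(m + 1), Xp(m + 1), Yp(m + 1),
                   Mc(m + 1), Xc(m + 1), Yc(m + 1);
  // row 0: leading gap in a (consuming b) is penalized but carries no columns
  Mp[0] = {0, 0, 0}; Xp[0] = {0, 0, 0}; Yp[0] = {0, 0, 0};
  for (int j = 1; j <= m; ++j) {
    Mp[j] = none; Xp[j] = none;
    Yp[j] = {-gap_run(j, gap_open, gap_ext), 0, 0};
  }
  Tri best = none;
  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1];
    Mc[0] = none; Yc[0] = none;
    Xc[0] = {-gap_run(i, gap_open, gap_ext), 0, 0};
    for (int j = 1; j <= m; ++j) {
      const bool eq = ai == b[j - 1];
      const int s = eq ? match_s : mismatch_s;
      // M from (i-1, j-1)
      Tri p = Mp[j - 1];
      if (tri_better(Xp[j - 1], p)) p = Xp[j - 1];
      if (tri_better(Yp[j - 1], p)) p = Yp[j - 1];
      if (p.s <= NEG / 2) Mc[j] = none;
      else Mc[j] = {p.s + s, p.m + (eq ? 1 : 0), p.c + 1};
      // X (gap in b, consumes a) from (i-1, j)
      Tri q1 = {Mp[j].s - gap_open, Mp[j].m, Mp[j].c};
      Tri q2 = {Xp[j].s - gap_ext, Xp[j].m, Xp[j].c};
      Tri q3 = {Yp[j].s - gap_open, Yp[j].m, Yp[j].c};
      Tri q = q1;
      if (tri_better(q2, q)) q = q2;
      if (tri_better(q3, q)) q = q3;
      if (q.s <= NEG / 2) Xc[j] = none;
      else Xc[j] = {q.s, q.m, q.c + 1};
      // Y (gap in a, consumes b) from (i, j-1)
      Tri r1 = {Mc[j - 1].s - gap_open, Mc[j - 1].m, Mc[j - 1].c};
      Tri r2 = {Xc[j - 1].s - gap_open, Xc[j - 1].m, Xc[j - 1].c};
      Tri r3 = {Yc[j - 1].s - gap_ext, Yc[j - 1].m, Yc[j - 1].c};
      Tri r = r1;
      if (tri_better(r2, r)) r = r2;
      if (tri_better(r3, r)) r = r3;
      if (r.s <= NEG / 2) Yc[j] = none;
      else Yc[j] = {r.s, r.m, r.c + 1};
    }
    // end candidates at (i, m): remaining a[i+1..n] is a trailing gap in b,
    // penalized (cheaper when it extends a current X run) but column-free
    {
      const int k = n - i;
      Tri e1 = {Mc[m].s - gap_run(k, gap_open, gap_ext), Mc[m].m, Mc[m].c};
      Tri e2 = {Xc[m].s - (k > 0 ? k * gap_ext : 0), Xc[m].m, Xc[m].c};
      Tri e3 = {Yc[m].s - gap_run(k, gap_open, gap_ext), Yc[m].m, Yc[m].c};
      if (Mc[m].s > NEG / 2 && tri_better(e1, best)) best = e1;
      if (Xc[m].s > NEG / 2 && tri_better(e2, best)) best = e2;
      if (Yc[m].s > NEG / 2 && tri_better(e3, best)) best = e3;
    }
    if (i == n) {
      // end candidates at (n, j): remaining b is a trailing gap in a
      for (int j = 0; j < m; ++j) {
        const int k = m - j;
        Tri e1 = {Mc[j].s - gap_run(k, gap_open, gap_ext), Mc[j].m, Mc[j].c};
        Tri e2 = {Xc[j].s - gap_run(k, gap_open, gap_ext), Xc[j].m, Xc[j].c};
        Tri e3 = {Yc[j].s - k * gap_ext, Yc[j].m, Yc[j].c};
        if (Mc[j].s > NEG / 2 && tri_better(e1, best)) best = e1;
        if (Xc[j].s > NEG / 2 && tri_better(e2, best)) best = e2;
        if (Yc[j].s > NEG / 2 && tri_better(e3, best)) best = e3;
      }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  out.score = best.s; out.match = best.m; out.cols = best.c;
}

static double identity_of(const Cell& c) {
  if (c.cols <= 0) return 0.0;
  return (double) c.match / (double) c.cols;
}

// [[Rcpp::export]]
List cpp_align_identity(std::string a, std::string b,
                        int match = 1, int mismatch = -1,
                        int gap_open = 2, int gap_ext = 1) {
  std::vector<int> va, vb;
  enc(a, va); enc(b, vb);
  Cell c;
  align_pair(va, vb, match, mismatch, gap_open, gap_ext, c);
  return List::create(_["identity"] = identity_of(c),
                      _["score"] = c.score,
                      _["matches"] = c.match,
                      _["columns"] = c.cols);
}

// Exhaustive top-hit search: every query against every reference, maximum
// identity wins; ties go to the reference appearing first (callers pass
// references ordered by id). tie_count counts references at the maximum.
// [[Rcpp::export]]
List cpp_top_hits(CharacterVector queries, CharacterVector refs,
                  int match = 1, int mismatch = -1,
                  int gap_open = 2, int gap_ext = 1) {
  const int nq = queries.size(), nr = refs.size();
  std::vector<std::vector<int>> rv(nr);
  for (int r = 0; r < nr; ++r) enc(as<std::string>(refs[r]), rv[r]);
  IntegerVector best_idx(nq);
  NumericVector best_id(nq);
  IntegerVector ties(nq);
  std::vector<int> qv;
  for (int q = 0; q < nq; ++q) {
    enc(as<std::string>(queries[q]), qv);
    double bi = -1.0; int bix = -1; int tc = 0;
    for (int r = 0; r < nr; ++r) {
      double id;
      if (qv.size() == rv[r].size() &&
          std::memcmp(qv.data(), rv[r].data(), qv.size() * sizeof(int)) == 0) {
        id = 1.0;
      } else {
        Cell c;
        align_pair(qv, rv[r], match, mismatch, gap_open, gap_ext, c);
        id = identity_of(c);
      }
      if (id > bi) { bi = id; bix = r; tc = 1; }
      else if (id == bi) { ++tc; }
    }
    best_idx[q] = bix + 1;
    best_id[q] = bi;
    ties[q] = tc;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["index"] = best_idx, _["identity"] = best_id,
                      _["tie_count"] = ties);
}

// Greedy centroid clustering: sequences are visited in the given
// (abundance-sorted) order; each joins the first centroid at identity >=
// threshold, otherwise founds a new centroid. Returns 1-based centroid index
// per sequence (into the input order) and the achieved identity.
// [[Rcpp::export]]
List cpp_greedy_cluster(CharacterVector seqs, double threshold,
                        int match = 1, int mismatch = -1,
                        int gap_open = 2, int gap_ext = 1) {
  const int n = seqs.size();
  std::vector<std::vector<int>> enc_seqs(n);
  for (int i = 0; i < n; ++i) enc(as<std::string>(seqs[i]), enc_seqs[i]);
  std::vector<int> centroids;
  IntegerVector assign(n);
  NumericVector idy(n);
  for (int i = 0; i < n; ++i) {
    int hit = -1; double hid = 0.0;
    for (size_t c = 0; c < centroids.size(); ++c) {
      const std::vector<int>& cs = enc_seqs[centroids[c]];
      double id;
      if (enc_seqs[i].size() == cs.size() &&
          std::memcmp(enc_seqs[i].data(), cs.data(), cs.size() * sizeof(int)) == 0) {
        id = 1.0;
      } else {
        Cell cc;
        align_pair(enc_seqs[i], cs, match, mismatch, gap_open, gap_ext, cc);
        id = identity_of(cc);
      }
      if (id >= threshold) { hit = centroids[c]; hid = id; break; }
    }
    if (hit < 0) {
      centroids.push_back(i);
      assign[i] = i + 1;
      idy[i] = 1.0;
    } else {
      assign[i] = hit + 1;
      idy[i] = hid;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["centroid"] = assign, _["identity"] = idy);
}

// IUPAC bitmask per character (A=1, C=2, G=4, T=8); degenerate codes are
// unions. A window position mismatches when the base masks do not intersect.
static inline int iupac_mask(char c) {
  switch (c) {
    case 'A': return 1; case 'C': return 2; case 'G': return 4; case 'T': return 8;
    case 'U': return 8;
    case 'R': return 1 | 4; case 'Y': return 2 | 8; case 'S': return 2 | 4;
    case 'W': return 1 | 8; case 'K': return 4 | 8; case 'M': return 1 | 2;
    case 'B': return 2 | 4 | 8; case 'D': return 1 | 4 | 8;
    case 'H': return 1 | 2 | 8; case 'V': return 1 | 2 | 4;
    case 'N': return 1 | 2 | 4 | 8;
    default: return 0;
  }
}

// Leftmost window within [start_lo, start_hi] (1-based, inclusive) whose
// mismatch count against the IUPAC primer is <= max_mismatch.
// Returns c(pos, mismatches) or c(NA, NA).
// [[Rcpp::export]]
IntegerVector cpp_scan_primer(std::string seq, std::string primer,
                              int max_mismatch, int start_lo, int start_hi) {
  const int L = (int) seq.size(), k = (int) primer.size();
  std::vector<int> pm(k), sm(L);
  for (int j = 0; j < k; ++j) pm[j] = iupac_mask(primer[j]);
  for (int i = 0; i < L; ++i) sm[i] = iupac_mask(seq[i]);
  if (start_lo < 1) start_lo = 1;
  if (start_hi > L - k + 1) start_hi = L - k + 1;
  for (int s = start_lo; s <= start_hi; ++s) {
    int mm = 0;
    for (int j = 0; j < k && mm <= max_mismatch; ++j) {
      if ((pm[j] & sm[s - 1 + j]) == 0) ++mm;
    }
    if (mm <= max_mismatch) {
      return IntegerVector::create(s, mm);
    }
  }
  return IntegerVector::create(NA_INTEGER, NA_INTEGER);
}
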