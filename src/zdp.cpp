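// Zebraic (feature-weighted) semi-global alignment core.
//
// Conventions: i indexes the query (rows, 1..m), j the reference (columns,
// 1..n). Three channels per cell: M (diagonal), E (gap in the query,
// consuming a reference column; penalized with that column's class), F (gap
// in the reference, consuming a query row; penalized with the class of the
// most recently consumed reference column). H = max(M, E, F). Semi-global
// boundary rules: first row and first column are 0 (free query/reference
// overhang at the start), traceback starts from the maximum cell of the
// last reference column (smallest query row on ties) so the reference is
// fully covered at the end; reference columns left of the path start are
// emitted as free deletions.
//
// The traceback matrix stores the argmax subset of {M, E, F} per cell
// (composite labels on ties) plus two extension bits recording whether each
// gap channel used extension, so traceback reconstructs a score-optimal
// path deterministically: continue the current move type when it is among
// the cell's options, otherwise MATCH > DELETION > INSERTION.

#include <Rcpp.h>
#include <cstdint>
#include <limits>
#include <vector>
#include <array>
#include <algorithm>

using namespace Rcpp;

static const uint8_t BIT_M = 1, BIT_E = 2, BIT_F = 4, BIT_EEXT = 8, BIT_FEXT = 16;

struct Profile {
  int match[5], mismatch[5], gopen[5], gext[5];
};

static Profile make_profile(const IntegerMatrix& prof) {
  if (prof.nrow() != 5 || prof.ncol() != 4)
    stop("profile matrix must be 5x4");
  Profile P;
  for (int c = 0; c < 5; ++c) {
    P.match[c] = prof(c, 0);
    P.mismatch[c] = prof(c, 1);
    P.gopen[c] = prof(c, 2);
    P.gext[c] = prof(c, 3);
  }
  return P;
}

// Generic block fill. row0[j] (j=0..n) and col0[i] (i=0..m) carry the
// boundary H values: all zero for semi-global mode, affine gap runs for
// anchored sliding-window blocks. Captures H of the last column and last
// row for boundary-cell selection.
static void fill_block(const char* r, int n, const char* q, int m,
                       const int* cls, const Profile& P,
                       const std::vector<int>& row0, const std::vector<int>& col0,
                       std::vector<uint8_t>& tb,
                       std::vector<int>& HlastCol, std::vector<int>& HlastRow) {
  std::vector<int> Hprev(col0), Hcur(m + 1, 0), E(m + 1, 0);
  tb.assign((size_t)m * n, 0);
  HlastRow.assign(n + 1, 0);
  HlastRow[0] = col0[m];
  if (n == 0) { HlastCol = Hprev; return; }
  for (int j = 1; j <= n; ++j) {
    const int c = cls[j - 1];
    const int mt = P.match[c], mm = P.mismatch[c];
    const int go = P.gopen[c], ge = P.gext[c];
    const char rc = r[j - 1];
    Hcur[0] = row0[j];
    int F = 0;
    for (int i = 1; i <= m; ++i) {
      const int M = Hprev[i - 1] + (q[i - 1] == rc ? mt : mm);
      const int Eopen = Hprev[i] - go;
      int newE; bool eext;
      if (j == 1) { newE = Eopen; eext = false; }
      else {
        const int Eext = E[i] - ge;
        eext = (Eext >= Eopen);
        newE = eext ? Eext : Eopen;
      }
      const int Fopen = Hcur[i - 1] - go;
      int newF; bool fext;
      if (i == 1) { newF = Fopen; fext = false; }
      else {
        const int Fext = F - ge;
        fext = (Fext >= Fopen);
        newF = fext ? Fext : Fopen;
      }
      int H = M;
      if (newE > H) H = newE;
      if (newF > H) H = newF;
      uint8_t bits = 0;
      if (M == H) bits |= BIT_M;
      if (newE == H) bits |= BIT_E;
      if (newF == H) bits |= BIT_F;
      if (eext) bits |= BIT_EEXT;
      if (fext) bits |= BIT_FEXT;
      tb[(size_t)(j - 1) * m + (i - 1)] = bits;
      Hcur[i] = H; E[i] = newE; F = newF;
    }
    HlastRow[j] = Hcur[m];
    std::swap(Hprev, Hcur);
  }
  HlastCol = Hprev;
}

struct Traceback {
  std::string ra, qa;  // aligned reference / query, block-local, forward order
  int istart, jstart;  // path start node within the block
};

// Trace from (i, j) toward (0, 0). In anchored mode the row-0 / column-0
// remainders are paid gap runs and are emitted; in semi-global mode the
// column-0 remainder is a free query overhang (clipped) and the row-0
// remainder is emitted as free deletions.
static Traceback trace_block(const char* r, const char* q, int m,
                             const std::vector<uint8_t>& tb,
                             int i, int j, bool anchored) {
  std::string ra, qa;  // built reversed
  int state = 0;     // 0 = H, 1 = E (deletion), 2 = F (insertion)
  int lastmove = 0;  // 0 none, 1 match, 2 deletion, 3 insertion
  while (i > 0 && j > 0) {
    const uint8_t bits = tb[(size_t)(j - 1) * m + (i - 1)];
    if (state == 0) {
      int choice;
      if (lastmove == 2 && (bits & BIT_E)) choice = 2;
      else if (lastmove == 3 && (bits & BIT_F)) choice = 3;
      else if (bits & BIT_M) choice = 1;
      else if (bits & BIT_E) choice = 2;
      else choice = 3;
      if (choice == 1) {
        ra.push_back(r[j - 1]); qa.push_back(q[i - 1]);
        --i; --j; lastmove = 1;
      } else if (choice == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      ra.push_back(r[j - 1]); qa.push_back('-');
      lastmove = 2; --j;
      state = (bits & BIT_EEXT) ? 1 : 0;
    } else {
      ra.push_back('-'); qa.push_back(q[i - 1]);
      lastmove = 3; --i;
      state = (bits & BIT_FEXT) ? 2 : 0;
    }
  }
  Traceback out;
  out.istart = i; out.jstart = j;
  if (anchored) {
    while (j > 0) { ra.push_back(r[j - 1]); qa.push_back('-'); --j; }
    while (i > 0) { ra.push_back('-'); qa.push_back(q[i - 1]); --i; }
    out.istart = 0; out.jstart = 0;
  } else {
    // leading unconsumed reference: free deletions; query prefix clipped
    while (j > 0) { ra.push_back(r[j - 1]); qa.push_back('-'); --j; }
    out.jstart = 0;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(qa.begin(), qa.end());
  out.ra = ra; out.qa = qa;
  return out;
}

static int pick_last_col(const std::vector<int>& HlastCol, int m) {
  int besti = 0, best = HlastCol[0];
  for (int i = 1; i <= m; ++i)
    if (HlastCol[i] > best) { best = HlastCol[i]; besti = i; }
  return besti;
}

static List aln_result(long long score, const std::string& ra, const std::string& qa,
                       int qstart, int qend, int width) {
  return List::create(
    _["score"] = (double)score,
    _["ref_aligned"] = ra,
    _["query_aligned"] = qa,
    _["qstart"] = qstart,
    _["qend"] = qend,
    _["width"] = width);
}

// [[Rcpp::export]]
List zdp_align_cpp(std::string ref, std::string query, IntegerVector cls,
                   IntegerMatrix prof, bool return_tb = false) {
  const int n = ref.size(), m = query.size();
  if (n == 0 || m == 0) stop("empty reference or query");
  if (cls.size() != n) stop("feature track length must equal reference length");
  Profile P = make_profile(prof);
  std::vector<int> row0(n + 1, 0), col0(m + 1, 0);
  std::vector<uint8_t> tb;
  std::vector<int> HlastCol, HlastRow;
  fill_block(ref.c_str(), n, query.c_str(), m, cls.begin(), P, row0, col0,
             tb, HlastCol, HlastRow);
  const int besti = pick_last_col(HlastCol, m);
  Traceback t = trace_block(ref.c_str(), query.c_str(), m, tb, besti, n, false);
  List out = aln_result(HlastCol[besti], t.ra, t.qa, t.istart, besti, 32);
  if (return_tb) {
    RawVector rv((size_t)m * n);
    std::copy(tb.begin(), tb.end(), rv.begin());
    rv.attr("dim") = IntegerVector::create(m, n);
    out["tb"] = rv;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Striped equivalent: per-class query profiles, batched column evaluation
// with a lazy-F correction pass, and narrow integer score storage escalated
// 8 -> 16 -> 32 bits on saturation. Produces results identical to
// zdp_align_cpp (same integer math, same traceback bytes).

template <typename T>
static bool striped_fill(const std::string& r, const std::string& q,
                         const int* cls, const Profile& P,
                         std::vector<uint8_t>& tb, std::vector<int>& Hlast) {
  const int m = q.size(), n = r.size();
  const long TMIN = (long)std::numeric_limits<T>::min();
  const long TMAX = (long)std::numeric_limits<T>::max();
  for (int c = 0; c < 5; ++c) {
    if (P.match[c] > TMAX || P.mismatch[c] < TMIN ||
        P.gopen[c] > TMAX || P.gext[c] > TMAX) return false;
  }
  // per-class, per-residue query profile vectors, built on first use
  std::array<std::array<std::vector<T>, 256>, 5> qp;
  std::vector<T> Hprev(m + 1, (T)0), Hstore(m + 1, (T)0), Estore(m + 1, (T)0);
  std::vector<int> Mv(m + 1), Ev(m + 1), Hv(m + 1);
  std::vector<uint8_t> eext(m + 1), fext(m + 1);
  tb.assign((size_t)m * n, 0);
  for (int j = 1; j <= n; ++j) {
    const int c = cls[j - 1];
    const unsigned char rc = (unsigned char)r[j - 1];
    std::vector<T>& pv = qp[c][rc];
    if (pv.empty()) {
      pv.resize(m);
      for (int i = 0; i < m; ++i)
        pv[i] = (T)(q[i] == (char)rc ? P.match[c] : P.mismatch[c]);
    }
    const int go = P.gopen[c], ge = P.gext[c];
    // batch pass: diagonal and horizontal (E) channels
    for (int i = 1; i <= m; ++i) {
      Mv[i] = (int)Hprev[i - 1] + (int)pv[i - 1];
      const int Eopen = (int)Hprev[i] - go;
      if (j == 1) { Ev[i] = Eopen; eext[i] = 0; }
      else {
        const int Eext = (int)Estore[i] - ge;
        if (Eext >= Eopen) { Ev[i] = Eext; eext[i] = 1; }
        else { Ev[i] = Eopen; eext[i] = 0; }
      }
      Hv[i] = Mv[i] > Ev[i] ? Mv[i] : Ev[i];
    }
    // lazy-F correction pass down the column
    int F = 0;
    bool sat = false;
    for (int i = 1; i <= m; ++i) {
      const int Hup = (i == 1) ? 0 : Hv[i - 1];
      const int Fopen = Hup - go;
      int newF;
      if (i == 1) { newF = Fopen; fext[i] = 0; }
      else {
        const int Fext = F - ge;
        if (Fext >= Fopen) { newF = Fext; fext[i] = 1; }
        else { newF = Fopen; fext[i] = 0; }
      }
      if (newF > Hv[i]) Hv[i] = newF;
      F = newF;
      uint8_t bits = 0;
      if (Mv[i] == Hv[i]) bits |= BIT_M;
      if (Ev[i] == Hv[i]) bits |= BIT_E;
      if (newF == Hv[i]) bits |= BIT_F;
      if (eext[i]) bits |= BIT_EEXT;
      if (fext[i]) bits |= BIT_FEXT;
      tb[(size_t)(j - 1) * m + (i - 1)] = bits;
      if (Hv[i] < TMIN || Hv[i] > TMAX || Ev[i] < TMIN || Ev[i] > TMAX ||
          newF < TMIN || newF > TMAX) sat = true;
    }
    if (sat) return false;
    for (int i = 1; i <= m; ++i) { Hstore[i] = (T)Hv[i]; Estore[i] = (T)Ev[i]; }
    Hstore[0] = 0;
    std::swap(Hprev, Hstore);
  }
  Hlast.assign(m + 1, 0);
  for (int i = 0; i <= m; ++i) Hlast[i] = (int)Hprev[i];
  return true;
}

// [[Rcpp::export]]
List zsdp_align_cpp(std::string ref, std::string query, IntegerVector cls,
                    IntegerMatrix prof) {
  const int n = ref.size(), m = query.size();
  if (n == 0 || m == 0) stop("empty reference or query");
  if (cls.size() != n) stop("feature track length must equal reference length");
  Profile P = make_profile(prof);
  std::vector<uint8_t> tb;
  std::vector<int> Hlast;
  int width = 8;
  if (!striped_fill<int8_t>(ref, query, cls.begin(), P, tb, Hlast)) {
    width = 16;
    if (!striped_fill<int16_t>(ref, query, cls.begin(), P, tb, Hlast)) {
      width = 32;
      striped_fill<int32_t>(ref, query, cls.begin(), P, tb, Hlast);
    }
  }
  const int besti = pick_last_col(Hlast, m);
  Traceback t = trace_block(ref.c_str(), query.c_str(), m, tb, besti, n, false);
  return aln_result(Hlast[besti], t.ra, t.qa, t.istart, besti, width);
}

// ---------------------------------------------------------------------------
// Sliding-window driver: tiles the DP space with window x window blocks, the
// maximum cell of each block's last row or last column anchoring the next
// block's origin. With window >= max(m, n) the single block IS the
// semi-global fill, so the result equals zdp_align exactly.

// [[Rcpp::export]]
List sliding_align_cpp(std::string ref, std::string query, IntegerVector cls,
                       IntegerMatrix prof, int window) {
  const int n = ref.size(), m = query.size();
  if (n == 0 || m == 0) stop("empty reference or query");
  if (cls.size() != n) stop("feature track length must equal reference length");
  if (window < 2) stop("window_size must be >= 2");
  Profile P = make_profile(prof);

  if (window >= std::max(m, n)) return zdp_align_cpp(ref, query, cls, prof, false);

  const char* r = ref.c_str();
  const char* q = query.c_str();
  std::string Ra, Qa;
  long long total = 0;
  int i0 = 0, j0 = 0, qstart = 0, qend = m;
  bool first = true;
  std::vector<uint8_t> tb;
  std::vector<int> HlastCol, HlastRow;

  for (;;) {
    const int bi = std::min(window, m - i0);
    const int bj = std::min(window, n - j0);
    if (bi == 0) {
      // query exhausted: remaining reference is one paid deletion run
      for (int j = j0 + 1; j <= n; ++j) {
        const int c = cls[j - 1];
        total -= (j == j0 + 1) ? P.gopen[c] : P.gext[c];
        Ra.push_back(r[j - 1]); Qa.push_back('-');
      }
      break;
    }
    std::vector<int> row0(bj + 1, 0), col0(bi + 1, 0);
    if (!first) {
      for (int j = 1; j <= bj; ++j) {
        const int c = cls[j0 + j - 1];
        row0[j] = row0[j - 1] - ((j == 1) ? P.gopen[c] : P.gext[c]);
      }
      const int ic = cls[j0 - 1];  // class of the origin's reference column
      for (int i = 1; i <= bi; ++i)
        col0[i] = col0[i - 1] - ((i == 1) ? P.gopen[ic] : P.gext[ic]);
    }
    fill_block(r + j0, bj, q + i0, bi, cls.begin() + j0, P, row0, col0,
               tb, HlastCol, HlastRow);
    const bool final_block = (j0 + bj == n);
    if (final_block) {
      const int besti = pick_last_col(HlastCol, bi);
      Traceback t = trace_block(r + j0, q + i0, bi, tb, besti, bj, !first);
      if (first) qstart = t.istart;
      total += HlastCol[besti];
      Ra += t.ra; Qa += t.qa;
      qend = i0 + besti;
      break;
    }
    // boundary cell: last column scanned first (rows ascending), then last
    // row (columns ascending); strict > keeps the earliest maximum.
    int ci = 0, cj = bj, best = HlastCol[0];
    for (int i = 1; i <= bi; ++i)
      if (HlastCol[i] > best) { best = HlastCol[i]; ci = i; cj = bj; }
    for (int j = 0; j <= bj; ++j)
      if (HlastRow[j] > best) { best = HlastRow[j]; ci = bi; cj = j; }
    if (ci == 0 && cj == 0) stop("sliding window failed to advance");
    Traceback t = trace_block(r + j0, q + i0, bi, tb, ci, cj, !first);
    if (first) qstart = t.istart;
    total += best;
    Ra += t.ra; Qa += t.qa;
    i0 += ci; j0 += cj;
    first = false;
  }
  return aln_result(total, Ra, Qa, qstart, qend, 32);
}
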