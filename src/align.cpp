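#include <Rcpp.h>
#include <cstdint>
#include <climits>
#include <vector>
#include <string>
using namespace Rcpp;

// Global pairwise alignment with affine gap penalties where gap runs that
// touch either end of the alignment (terminal runs) are priced separately
// from interior runs.  A gap run in the query lies entirely at one query
// position i and is terminal iff i == 0 or i == m; likewise a gap run in
// the target is terminal iff j == 0 or j == n.  This lets the DP price
// terminal runs exactly by making the open/extend costs a function of the
// global row/column index.
//
// Two drivers share the cell recurrences:
//  * a full-matrix Gotoh DP with a one-byte-per-cell traceback, used when
//    the product of the lengths is small enough;
//  * a divide-and-conquer driver (Myers & Miller style) that splits on the
//    middle query row using linear-memory forward/backward passes and
//    recurses, falling back to the full DP on small blocks.  Only vertical
//    (gap-in-target) runs can cross a row split, so the combine step
//    considers an H-state and an F-state crossing per column.

typedef long long ll;
static const ll NEG = LLONG_MIN / 4;

struct Params {
  ll match, mismatch;
  ll oq_i, oq_t;  // open a gap in the query (consumes target), interior/terminal
  ll ot_i, ot_t;  // open a gap in the target (consumes query)
  ll ge_i, ge_t;  // extend, interior/terminal
};

static inline char normc(char c) {
  if (c >= 'a' && c <= 'z') c = (char)(c - 'a' + 'A');
  if (c == 'U') c = 'T';
  return c;
}

static int iupac_bits(char c) {
  switch (c) {
    case 'A': return 1; case 'C': return 2; case 'G': return 4; case 'T': return 8;
    case 'R': return 5; case 'Y': return 10; case 'S': return 6; case 'W': return 9;
    case 'K': return 12; case 'M': return 3; case 'B': return 14; case 'D': return 13;
    case 'H': return 11; case 'V': return 7; case 'N': return 15;
    default: return 15;  // unknown symbols behave like N
  }
}

static inline ll subst(char a, char b, const Params& p) {
  char na = normc(a), nb = normc(b);
  if (na == 'N' || nb == 'N') return 0;
  if (na == nb) return p.match;
  if (iupac_bits(na) & iupac_bits(nb)) return p.match;
  return p.mismatch;
}

// identity counts a column as a match only on textual equality after
// normalisation, never for N or merely-compatible ambiguity codes
static inline bool idmatch(char a, char b) {
  char na = normc(a), nb = normc(b);
  return na == nb && na != 'N';
}

struct Problem {
  const std::string* A;
  const std::string* B;
  int m, n;
  Params p;
  inline ll openE(int i) const { return (i == 0 || i == m) ? p.oq_t : p.oq_i; }
  inline ll extE(int i) const { return (i == 0 || i == m) ? p.ge_t : p.ge_i; }
  inline ll openF(int j) const { return (j == 0 || j == n) ? p.ot_t : p.ot_i; }
  inline ll extF(int j) const { return (j == 0 || j == n) ? p.ge_t : p.ge_i; }
  // ca(t)/cb(t): t-th consumed character (1-based) in forward or reversed order
  inline char ca(int t, bool rev) const { return rev ? (*A)[m - t] : (*A)[t - 1]; }
  inline char cb(int t, bool rev) const { return rev ? (*B)[n - t] : (*B)[t - 1]; }
};

// trace byte layout: bits 0-1 = H source (0 diag, 1 E, 2 F, 3 unreachable);
// bit 2 = E extended (vs opened); bit 3 = F extended (vs opened)
static const uint8_t H_DIAG = 0, H_E = 1, H_F = 2, H_NONE = 3;
static const uint8_t E_EXT = 4, F_EXT = 8;

// Full DP over global rows i0..i1, cols j0..j1.  startF: the path must
// enter the block mid-way through a vertical run at the top-left corner
// (the run's open cost is charged here).  endF: the path must leave the
// block mid-run at the bottom-right corner (score taken from the F state).
// Ops ('M' both, 'D' consumes target = gap in query, 'I' consumes query)
// are appended in alignment order.
static ll block_dp(const Problem& pr, int i0, int i1, int j0, int j1,
                   bool startF, bool endF, std::string& ops) {
  const int r = i1 - i0, c = j1 - j0;
  std::vector<uint8_t> tr((size_t)(r + 1) * (c + 1), H_NONE);
  std::vector<ll> Hprev(c + 1), Hcur(c + 1), F(c + 1, NEG);

  // local row 0 (global row i0)
  if (startF) {
    for (int j = 0; j <= c; ++j) Hprev[j] = NEG;
    F[0] = -pr.openF(j0);  // run opened at the corner, zero steps so far
  } else {
    Hprev[0] = 0;
    tr[0] = H_DIAG;
    ll oE = pr.openE(i0), eE = pr.extE(i0);
    for (int j = 1; j <= c; ++j) {
      Hprev[j] = -(oE + eE * (ll)j);
      tr[j] = (uint8_t)(H_E | (j > 1 ? E_EXT : 0));
    }
  }

  for (int i = 1; i <= r; ++i) {
    const int gi = i0 + i;
    uint8_t* trow = &tr[(size_t)i * (c + 1)];
    // local column 0
    {
      ll fo = Hprev[0] == NEG ? NEG : Hprev[0] - pr.openF(j0) - pr.extF(j0);
      ll fe = F[0] == NEG ? NEG : F[0] - pr.extF(j0);
      uint8_t bits = H_F;
      if (fo >= fe) F[0] = fo; else { F[0] = fe; bits |= F_EXT; }
      Hcur[0] = F[0];
      trow[0] = bits;
    }
    ll E = NEG;
    const ll oE = pr.openE(gi), eE = pr.extE(gi);
    const char ai = pr.ca(gi, false);
    for (int j = 1; j <= c; ++j) {
      const int gj = j0 + j;
      uint8_t bits = 0;
      ll diag = (Hprev[j - 1] == NEG) ? NEG : Hprev[j - 1] + subst(ai, pr.cb(gj, false), pr.p);
      ll eo = Hcur[j - 1] == NEG ? NEG : Hcur[j - 1] - oE - eE;
      ll ee = E == NEG ? NEG : E - eE;
      if (eo >= ee) E = eo; else { E = ee; bits |= E_EXT; }
      ll fo = Hprev[j] == NEG ? NEG : Hprev[j] - pr.openF(gj) - pr.extF(gj);
      ll fe = F[j] == NEG ? NEG : F[j] - pr.extF(gj);
      if (fo >= fe) F[j] = fo; else { F[j] = fe; bits |= F_EXT; }
      // preference on ties: diagonal, then gap-in-query, then gap-in-target
      ll best;
      uint8_t src;
      if (diag >= E && diag >= F[j]) { best = diag; src = H_DIAG; }
      else if (E >= F[j]) { best = E; src = H_E; }
      else { best = F[j]; src = H_F; }
      if (best <= NEG / 2) src = H_NONE;
      Hcur[j] = best;
      trow[j] = (uint8_t)(bits | src);
    }
    std::swap(Hprev, Hcur);
  }

  ll score = endF ? F[c] : Hprev[c];
  if (r == 0 && endF) Rcpp::stop("internal: endF on an empty block");

  // traceback
  std::string rev;
  int i = r, j = c;
  char state = endF ? 'F' : 'H';
  while (!(i == 0 && j == 0)) {
    const uint8_t b = tr[(size_t)i * (c + 1) + j];
    if (state == 'H') {
      const uint8_t src = b & 3;
      if (src == H_DIAG) {
        if (i == 0 || j == 0) Rcpp::stop("internal: bad traceback");
        rev.push_back('M'); --i; --j;
      } else if (src == H_E) state = 'E';
      else if (src == H_F) state = 'F';
      else Rcpp::stop("internal: unreachable cell in traceback");
    } else if (state == 'E') {
      rev.push_back('D');
      state = (b & E_EXT) ? 'E' : 'H';
      --j;
    } else {  // F
      rev.push_back('I');
      state = (b & F_EXT) ? 'F' : 'H';
      --i;
    }
  }
  ops.append(rev.rbegin(), rev.rend());
  return score;
}

// forward (or mirrored) linear-memory pass over transformed rows t0..t1,
// cols u0..u1; returns the H and F state vectors at row t1.
static void lin_pass(const Problem& pr, bool rev, int t0, int t1, int u0, int u1,
                     bool startF, std::vector<ll>& H, std::vector<ll>& F) {
  const int c = u1 - u0;
  H.assign(c + 1, NEG);
  F.assign(c + 1, NEG);
  if (startF) {
    F[0] = -pr.openF(rev ? pr.n - u0 : u0);
  } else {
    H[0] = 0;
    const int gi = rev ? pr.m - t0 : t0;
    ll oE = pr.openE(gi), eE = pr.extE(gi);
    for (int j = 1; j <= c; ++j) H[j] = -(oE + eE * (ll)j);
  }
  std::vector<ll> Hnew(c + 1);
  for (int t = t0 + 1; t <= t1; ++t) {
    const int gi = rev ? pr.m - t : t;  // boundary index for E pricing
    const char ai = pr.ca(t, rev);
    {
      const int gj = rev ? pr.n - u0 : u0;
      ll fo = H[0] == NEG ? NEG : H[0] - pr.openF(gj) - pr.extF(gj);
      ll fe = F[0] == NEG ? NEG : F[0] - pr.extF(gj);
      F[0] = fo >= fe ? fo : fe;
      Hnew[0] = F[0];
    }
    ll E = NEG;
    const ll oE = pr.openE(gi), eE = pr.extE(gi);
    for (int j = 1; j <= c; ++j) {
      const int u = u0 + j;
      const int gj = rev ? pr.n - u : u;
      ll diag = (H[j - 1] == NEG) ? NEG : H[j - 1] + subst(ai, pr.cb(u, rev), pr.p);
      ll eo = Hnew[j - 1] == NEG ? NEG : Hnew[j - 1] - oE - eE;
      ll ee = E == NEG ? NEG : E - eE;
      E = eo >= ee ? eo : ee;
      ll fo = H[j] == NEG ? NEG : H[j] - pr.openF(gj) - pr.extF(gj);
      ll fe = F[j] == NEG ? NEG : F[j] - pr.extF(gj);
      F[j] = fo >= fe ? fo : fe;
      ll best = diag;
      if (E > best) best = E;
      if (F[j] > best) best = F[j];
      Hnew[j] = best;
    }
    std::swap(H, Hnew);
  }
}

static const long BLOCK_CELLS = 1L << 21;

static ll solve_linear(const Problem& pr, int i0, int i1, int j0, int j1,
                       bool startF, bool endF, std::string& ops) {
  const long cells = (long)(i1 - i0 + 1) * (long)(j1 - j0 + 1);
  if (i1 - i0 <= 1 || j1 - j0 <= 1 || cells <= BLOCK_CELLS)
    return block_dp(pr, i0, i1, j0, j1, startF, endF, ops);

  const int imid = (i0 + i1) / 2;
  std::vector<ll> HF, FF, HB, FB;
  lin_pass(pr, false, i0, imid, j0, j1, startF, HF, FF);
  // mirrored pass over rows imid..i1: transformed rows m-i1 .. m-imid
  lin_pass(pr, true, pr.m - i1, pr.m - imid, pr.n - j1, pr.n - j0, endF, HB, FB);

  ll best = NEG;
  int jmid = -1;
  bool crossF = false;
  const int c = j1 - j0;
  for (int j = 0; j <= c; ++j) {
    const int gj = j0 + j;
    const ll hb = HB[c - j], fb = FB[c - j];
    if (HF[j] > NEG / 2 && hb > NEG / 2) {
      ll v = HF[j] + hb;
      if (v > best) { best = v; jmid = gj; crossF = false; }
    }
    if (FF[j] > NEG / 2 && fb > NEG / 2) {
      // both halves charged the open of the crossing run; add one back
      ll v = FF[j] + fb + pr.openF(gj);
      if (v > best) { best = v; jmid = gj; crossF = true; }
    }
  }
  if (jmid < 0) Rcpp::stop("internal: no feasible split");
  ll s1 = solve_linear(pr, i0, imid, j0, jmid, startF, crossF, ops);
  ll s2 = solve_linear(pr, imid, i1, jmid, j1, crossF, endF, ops);
  (void)s1; (void)s2;
  return best;
}

static List summarise(const Problem& pr, ll score, const std::string& ops) {
  // collapse runs into a CIGAR and classify columns
  std::string cigar;
  {
    char prev = 0; long run = 0;
    for (size_t k = 0; k <= ops.size(); ++k) {
      char o = k < ops.size() ? ops[k] : 0;
      if (o == prev) { ++run; continue; }
      if (prev) { cigar += std::to_string(run); cigar.push_back(prev); }
      prev = o; run = 1;
    }
  }
  long firstM = -1, lastM = -1;
  for (size_t k = 0; k < ops.size(); ++k)
    if (ops[k] == 'M') { if (firstM < 0) firstM = (long)k; lastM = (long)k; }
  long matches = 0, mismatches = 0, internal_gap = 0, terminal_gap = 0, runs = 0;
  long qlo = 0, qhi = 0, tlo = 0, thi = 0;
  int qi = 0, ti = 0;
  char prevop = 'M';
  std::string qrow, trow;
  qrow.reserve(ops.size()); trow.reserve(ops.size());
  for (size_t k = 0; k < ops.size(); ++k) {
    const char o = ops[k];
    if (o == 'M') {
      ++qi; ++ti;
      if (qlo == 0) { qlo = qi; tlo = ti; }
      qhi = qi; thi = ti;
      if (idmatch((*pr.A)[qi - 1], (*pr.B)[ti - 1])) ++matches; else ++mismatches;
      qrow.push_back((*pr.A)[qi - 1]); trow.push_back((*pr.B)[ti - 1]);
    } else {
      const bool terminal = firstM < 0 || (long)k < firstM || (long)k > lastM;
      if (terminal) ++terminal_gap;
      else {
        ++internal_gap;
        if (o != prevop) ++runs;
      }
      if (o == 'D') { ++ti; qrow.push_back('-'); trow.push_back((*pr.B)[ti - 1]); }
      else { ++qi; qrow.push_back((*pr.A)[qi - 1]); trow.push_back('-'); }
    }
    prevop = o;
  }
  return List::create(
    _["score"] = (double)score,
    _["cigar"] = cigar,
    _["columns"] = (double)ops.size(),
    _["matches"] = (double)matches,
    _["mismatches"] = (double)mismatches,
    _["internal_gap_columns"] = (double)internal_gap,
    _["terminal_gap_columns"] = (double)terminal_gap,
    _["internal_gap_runs"] = (double)runs,
    _["qlo"] = (double)qlo, _["qhi"] = (double)qhi,
    _["tlo"] = (double)tlo, _["thi"] = (double)thi,
    _["qrow"] = qrow, _["trow"] = trow);
}

static Params parse_params(const List& par) {
  Params p;
  p.match = (ll)as<double>(par["match"]);
  p.mismatch = (ll)as<double>(par["mismatch"]);
  p.oq_i = (ll)as<double>(par["gap_open_interior_query"]);
  p.oq_t = (ll)as<double>(par["gap_open_terminal_query"]);
  p.ot_i = (ll)as<double>(par["gap_open_interior_target"]);
  p.ot_t = (ll)as<double>(par["gap_open_terminal_target"]);
  p.ge_i = (ll)as<double>(par["gap_extend_interior"]);
  p.ge_t = (ll)as<double>(par["gap_extend_terminal"]);
  return p;
}

// [[Rcpp::export(name = ".align_cpp")]]
List align_cpp(const std::string& a, const std::string& b, List par, bool linear) {
  if (a.empty() || b.empty()) Rcpp::stop("sequences must be non-empty");
  Problem pr;
  pr.A = &a; pr.B = &b;
  pr.m = (int)a.size(); pr.n = (int)b.size();
  pr.p = parse_params(par);
  std::string ops;
  ll score;
  if (linear) score = solve_linear(pr, 0, pr.m, 0, pr.n, false, false, ops);
  else score = block_dp(pr, 0, pr.m, 0, pr.n, false, false, ops);
  return summarise(pr, score, ops);
}

// [[Rcpp::export(name = ".subst_score_cpp")]]
double subst_score_cpp(const std::string& a, const std::string& b, List par) {
  Params p = parse_params(par);
  return (double)subst(a[0], b[0], p);
}
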