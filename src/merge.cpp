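#include <Rcpp.h>
#include <string>
#include <vector>
#include <utility>
#include <algorithm>
using namespace Rcpp;

// Exhaustive scan over ungapped overlap placements of a forward read and a
// reverse-complemented reverse read.  `shift` is the start of the reverse
// read relative to the forward read's first base: shift >= 0 is a normal
// placement, shift < 0 is staggered (the reverse 3' end overhangs the
// forward 5' start).  Per-column scores come from lookup tables indexed by
// the two quality values, one table for observed-equal columns and one for
// observed-different columns.  Ties in score are resolved in favour of the
// smaller overlap (placements are scanned in order of increasing overlap).

static inline char mnorm(char c) {
  if (c >= 'a' && c <= 'z') c = (char)(c - 'a' + 'A');
  return c == 'U' ? 'T' : c;
}

// [[Rcpp::export(name = ".merge_scan_cpp")]]
List merge_scan_cpp(const std::string& f, const IntegerVector& fq,
                    const std::string& r, const IntegerVector& rq,
                    const NumericMatrix& eq_score, const NumericMatrix& diff_score,
                    int minovlen) {
  // staggered placements (shift < 0) are always scanned; whether a
  // staggered best placement is allowed is decided by the caller
  const int lf = (int)f.size(), lr = (int)r.size();
  const int smin = -(lr - minovlen);
  const int smax = lf - minovlen;

  // order shifts by increasing overlap so the first strict maximum wins
  std::vector<std::pair<int, int> > shifts;  // (overlap, shift)
  for (int s = smin; s <= smax; ++s) {
    int lo = s > 0 ? s : 0;
    int hi = (s + lr < lf) ? s + lr : lf;
    int ov = hi - lo;
    if (ov >= minovlen) shifts.push_back(std::make_pair(ov, s));
  }
  std::stable_sort(shifts.begin(), shifts.end());

  double best = -1e300;
  int best_shift = NA_INTEGER, best_ov = 0;
  for (size_t k = 0; k < shifts.size(); ++k) {
    const int s = shifts[k].second;
    const int lo = s > 0 ? s : 0;
    const int hi = (s + lr < lf) ? s + lr : lf;
    double sc = 0.0;
    for (int i = lo; i < hi; ++i) {
      const int q1 = fq[i], q2 = rq[i - s];
      if (mnorm(f[i]) == mnorm(r[i - s])) sc += eq_score(q1, q2);
      else sc += diff_score(q1, q2);
    }
    if (sc > best) { best = sc; best_shift = s; best_ov = shifts[k].first; }
  }
  if (best_shift == NA_INTEGER)
    return List::create(_["found"] = false);

  // count observed mismatches in the chosen overlap
  const int s = best_shift;
  const int lo = s > 0 ? s : 0;
  const int hi = (s + lr < lf) ? s + lr : lf;
  int diffs = 0;
  for (int i = lo; i < hi; ++i)
    if (mnorm(f[i]) != mnorm(r[i - s])) ++diffs;

  return List::create(_["found"] = true, _["shift"] = s, _["overlap"] = best_ov,
                      _["score"] = best, _["diffs"] = diffs,
                      _["staggered"] = (s < 0));
}
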