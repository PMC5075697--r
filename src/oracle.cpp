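#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Plain full-matrix reference scorer for the affine-gap global alignment
// model with terminal-gap pricing.  Deliberately written as a naive
// three-state DP (state = last emitted column) with complete matrices and
// no traceback, independent of the production aligner; used only for
// cross-checks.

static inline char onorm(char c) {
  if (c >= 'a' && c <= 'z') c = (char)(c - 'a' + 'A');
  return c == 'U' ? 'T' : c;
}

static int obits(char c) {
  switch (c) {
    case 'A': return 1; case 'C': return 2; case 'G': return 4; case 'T': return 8;
    case 'R': return 5; case 'Y': return 10; case 'S': return 6; case 'W': return 9;
    case 'K': return 12; case 'M': return 3; case 'B': return 14; case 'D': return 13;
    case 'H': return 11; case 'V': return 7;
    default: return 15;
  }
}

// [[Rcpp::export(name = ".align_score_oracle_cpp")]]
double align_score_oracle_cpp(const std::string& a, const std::string& b, List par) {
  const int m = (int)a.size(), n = (int)b.size();
  const double match = as<double>(par["match"]);
  const double mis = as<double>(par["mismatch"]);
  const double oqi = as<double>(par["gap_open_interior_query"]);
  const double oqt = as<double>(par["gap_open_terminal_query"]);
  const double oti = as<double>(par["gap_open_interior_target"]);
  const double ott = as<double>(par["gap_open_terminal_target"]);
  const double gei = as<double>(par["gap_extend_interior"]);
  const double get = as<double>(par["gap_extend_terminal"]);
  const double NA_ = -1e15;

  std::vector<std::vector<double> > M(m + 1, std::vector<double>(n + 1, NA_));
  std::vector<std::vector<double> > X(m + 1, std::vector<double>(n + 1, NA_));
  std::vector<std::vector<double> > Y(m + 1, std::vector<double>(n + 1, NA_));

  M[0][0] = 0.0;
  for (int j = 1; j <= n; ++j) X[0][j] = -(oqt + get * j);
  for (int i = 1; i <= m; ++i) Y[i][0] = -(ott + get * i);

  for (int i = 1; i <= m; ++i) {
    const char ca = onorm(a[i - 1]);
    for (int j = 1; j <= n; ++j) {
      const char cb = onorm(b[j - 1]);
      double s;
      if (ca == 'N' || cb == 'N') s = 0.0;
      else if (ca == cb) s = match;
      else if (obits(ca) & obits(cb)) s = match;
      else s = mis;
      double prev = M[i - 1][j - 1];
      if (X[i - 1][j - 1] > prev) prev = X[i - 1][j - 1];
      if (Y[i - 1][j - 1] > prev) prev = Y[i - 1][j - 1];
      if (prev > NA_ / 2) M[i][j] = prev + s;

      const double ox = (i == 0 || i == m) ? oqt : oqi;
      const double ex = (i == 0 || i == m) ? get : gei;
      double best = NA_;
      if (X[i][j - 1] > NA_ / 2 && X[i][j - 1] - ex > best) best = X[i][j - 1] - ex;
      if (M[i][j - 1] > NA_ / 2 && M[i][j - 1] - ox - ex > best) best = M[i][j - 1] - ox - ex;
      if (Y[i][j - 1] > NA_ / 2 && Y[i][j - 1] - ox - ex > best) best = Y[i][j - 1] - ox - ex;
      X[i][j] = best;

      const double oy = (j == 0 || j == n) ? ott : oti;
      const double ey = (j == 0 || j == n) ? get : gei;
      best = NA_;
      if (Y[i - 1][j] > NA_ / 2 && Y[i - 1][j] - ey > best) best = Y[i - 1][j] - ey;
      if (M[i - 1][j] > NA_ / 2 && M[i - 1][j] - oy - ey > best) best = M[i - 1][j] - oy - ey;
      if (X[i - 1][j] > NA_ / 2 && X[i - 1][j] - oy - ey > best) best = X[i - 1][j] - oy - ey;
      Y[i][j] = best;
    }
  }
  double out = M[m][n];
  if (X[m][n] > out) out = X[m][n];
  if (Y[m][n] > out) out = Y[m][n];
  return out;
}
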