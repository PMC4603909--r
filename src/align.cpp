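#include <Rcpp.h>
#include <climits>
#include <string>
#include <vector>
using namespace Rcpp;

// Global affine-gap alignment (Gotoh) over (score, matches) lexicographic
// value: among all optimal-score global alignments, the one with the
// maximal identity count. This makes the identity statistic well-defined
// without relying on a traceback tie-break. A gap of length L costs
// gap_open + gap_ext * L.

struct SM { int s; int m; };

static inline bool better(const SM &a, const SM &b) {
  return a.s > b.s || (a.s == b.s && a.m > b.m);
}
static inline SM lexmax(const SM &a, const SM &b) { return better(a, b) ? a : b; }

static const int NEG = INT_MIN / 4;

static SM align_pair(const std::string &a, const std::string &b,
                     int match, int mismatch, int gap_open, int gap_ext) {
  const int n = (int)a.size(), m = (int)b.size();
  const int open1 = gap_open + gap_ext; // cost of a 1-residue gap
  std::vector<SM> Mprev(m + 1), Xprev(m + 1), Mcur(m + 1), Xcur(m + 1);
  std::vector<SM> Yprev(m + 1), Ycur(m + 1);
  Mprev[0] = {0, 0};
  Xprev[0] = {NEG, 0};
  Yprev[0] = {NEG, 0};
  for (int j = 1; j <= m; ++j) {
    Mprev[j] = {NEG, 0};
    Xprev[j] = {NEG, 0};
    Yprev[j] = {-(gap_open + gap_ext * j), 0};
  }
  for (int i = 1; i <= n; ++i) {
    Mcur[0] = {NEG, 0};
    Xcur[0] = {-(gap_open + gap_ext * i), 0};
    Ycur[0] = {NEG, 0};
    for (int j = 1; j <= m; ++j) {
      // M: consume a[i-1] vs b[j-1]
      SM diag = lexmax(Mprev[j - 1], lexmax(Xprev[j - 1], Yprev[j - 1]));
      int eq = (a[i - 1] == b[j - 1]) ? 1 : 0;
      if (diag.s <= NEG / 2) Mcur[j] = {NEG, 0};
      else Mcur[j] = {diag.s + (eq ? match : mismatch), diag.m + eq};
      // X: gap in b (consume a[i-1])
      SM xo = lexmax(Mprev[j], Yprev[j]);
      SM x1 = {xo.s <= NEG / 2 ? NEG : xo.s - open1, xo.m};
      SM x2 = {Xprev[j].s <= NEG / 2 ? NEG : Xprev[j].s - gap_ext, Xprev[j].m};
      Xcur[j] = lexmax(x1, x2);
      // Y: gap in a (consume b[j-1])
      SM yo = lexmax(Mcur[j - 1], Xcur[j - 1]);
      SM y1 = {yo.s <= NEG / 2 ? NEG : yo.s - open1, yo.m};
      SM y2 = {Ycur[j - 1].s <= NEG / 2 ? NEG : Ycur[j - 1].s - gap_ext,
               Ycur[j - 1].m};
      Ycur[j] = lexmax(y1, y2);
    }
    std::swap(Mprev, Mcur);
    std::swap(Xprev, Xcur);
    std::swap(Yprev, Ycur);
  }
  return lexmax(Mprev[m], lexmax(Xprev[m], Yprev[m]));
}

// [[Rcpp::export]]
IntegerVector align_matches_cpp(std::string a, std::string b,
                                int match, int mismatch,
                                int gap_open, int gap_ext) {
  SM r = align_pair(a, b, match, mismatch, gap_open, gap_ext);
  return IntegerVector::create(_["score"] = r.s, _["matches"] = r.m);
}

// [[Rcpp::export]]
NumericMatrix similarity_matrix_cpp(CharacterVector A, CharacterVector B,
                                    int match, int mismatch,
                                    int gap_open, int gap_ext) {
  const int na = A.size(), nb = B.size();
  NumericMatrix out(na, nb);
  std::vector<std::string> as(na), bs(nb);
  for (int i = 0; i < na; ++i) as[i] = std::string(A[i]);
  for (int j = 0; j < nb; ++j) bs[j] = std::string(B[j]);
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      int shorter = (int)std::min(as[i].size(), bs[j].size());
      if (shorter == 0) { out(i, j) = NA_REAL; continue; }
      SM r = align_pair(as[i], bs[j], match, mismatch, gap_open, gap_ext);
      out(i, j) = (double)r.m / (double)shorter;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
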