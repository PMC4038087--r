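// Affine-gap global alignment (Needleman-Wunsch / Gotoh), full-matrix or
// banded. Gap of length k costs gap_open + k * gap_extend. Tie-breaking in
// traceback prefers diagonal (match/substitution) over gap-in-b (consume a)
// over gap-in-a (consume b), so alignments are deterministic.
#include <Rcpp.h>
#include <cstring>
#include <limits>
using namespace Rcpp;

static const double NEG = -std::numeric_limits<double>::infinity();

// state codes: 0 = M (diagonal), 1 = X (gap in b, consumes a), 2 = Y (gap in
// a, consumes b). Packed traceback byte: bits 0-1 pred of M, 2-3 pred of X,
// 4-5 pred of Y.

// [[Rcpp::export(name = ".nw_affine_cpp")]]
List nw_affine_cpp(IntegerVector a, IntegerVector b, NumericMatrix sm,
                   double gap_open, double gap_extend, int band) {
  const int n = a.size(), m = b.size();
  const double go = gap_open + gap_extend;  // cost of opening (first residue)
  const double ge = gap_extend;
  // band half-widths; full alignment when band < 0
  long bandL = band, bandU = band;
  if (band < 0) { bandL = n; bandU = m; }
  else {
    if (m > n) bandU += (m - n);
    if (n > m) bandL += (n - m);
    if (bandL > n) bandL = n;
    if (bandU > m) bandU = m;
  }

  const size_t W = (size_t)(bandL + bandU + 1);
  // rolling score rows indexed by column offset within the band
  std::vector<double> Mprev(W, NEG), Xprev(W, NEG), Yprev(W, NEG),
      Mcur(W, NEG), Xcur(W, NEG), Ycur(W, NEG);
  std::vector<unsigned char> tb((size_t)(n + 1) * W, 0);

  // column j maps to offset j - (i - bandL) in row i
  auto off = [&](int i, int j) -> long { return (long)j - ((long)i - bandL); };

  // row 0
  {
    int jmax = (int)std::min((long)m, bandU);
    long o0 = off(0, 0);
    Mprev[o0] = 0.0;
    for (int j = 1; j <= jmax; ++j) {
      long o = off(0, j);
      Yprev[o] = -(go + ge * (j - 1));
      tb[(size_t)0 * W + o] |= (2u << 4);  // Y from Y
    }
  }

  for (int i = 1; i <= n; ++i) {
    std::fill(Mcur.begin(), Mcur.end(), NEG);
    std::fill(Xcur.begin(), Xcur.end(), NEG);
    std::fill(Ycur.begin(), Ycur.end(), NEG);
    long jlo = (long)i - bandL, jhi = (long)i + bandU;
    if (jlo < 0) jlo = 0;
    if (jhi > m) jhi = m;
    for (long j = jlo; j <= jhi; ++j) {
      long o = off(i, j);
      unsigned char code = 0;
      if (j == 0) {
        Xcur[o] = -(go + ge * (i - 1));
        code |= (1u << 2);  // X from X
        tb[(size_t)i * W + o] = code;
        continue;
      }
      // M: from (i-1, j-1) -> offset in prev row = j-1 - (i-1-bandL) = o
      {
        double s = sm(a[i - 1], b[j - 1]);
        double m0 = Mprev[o], x0 = Xprev[o], y0 = Yprev[o];
        double best = m0; unsigned char p = 0;
        if (x0 > best) { best = x0; p = 1; }
        if (y0 > best) { best = y0; p = 2; }
        if (best > NEG) { Mcur[o] = best + s; code |= p; }
      }
      // X: from (i-1, j) -> offset o + 1 in prev row
      if (o + 1 < (long)W) {
        double m0 = Mprev[o + 1] - go, x0 = Xprev[o + 1] - ge,
               y0 = Yprev[o + 1] - go;
        double best = m0; unsigned char p = 0;
        if (x0 > best) { best = x0; p = 1; }
        if (y0 > best) { best = y0; p = 2; }
        if (best > NEG) { Xcur[o] = best; code |= (p << 2); }
      }
      // Y: from (i, j-1) -> offset o - 1 in current row
      if (o - 1 >= 0) {
        double m0 = Mcur[o - 1] - go, x0 = Xcur[o - 1] - go,
               y0 = Ycur[o - 1] - ge;
        double best = m0; unsigned char p = 0;
        if (x0 > best) { best = x0; p = 1; }
        if (y0 > best) { best = y0; p = 2; }
        if (best > NEG) { Ycur[o] = best; code |= (p << 4); }
      }
      tb[(size_t)i * W + o] = code;
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  long oe = off(n, m);
  if (oe < 0 || oe >= (long)W)
    stop("band too narrow for these sequence lengths");
  double sM = Mprev[oe], sX = Xprev[oe], sY = Yprev[oe];
  int state; double score;
  if (sM >= sX && sM >= sY) { state = 0; score = sM; }
  else if (sX >= sY) { state = 1; score = sX; }
  else { state = 2; score = sY; }
  if (score == NEG) stop("band too narrow: no feasible alignment path");

  // traceback: emit op string over {M = aligned pair, X = gap in b,
  // Y = gap in a}, reading predecessor choices from the packed bytes
  std::string ops;
  ops.reserve(n + m);
  int i = n; long j = m;
  while (i > 0 || j > 0) {
    unsigned char code = tb[(size_t)i * W + off(i, j)];
    if (state == 0) {
      ops.push_back('M');
      state = code & 3u;
      --i; --j;
    } else if (state == 1) {
      ops.push_back('X');
      state = (code >> 2) & 3u;
      --i;
    } else {
      ops.push_back('Y');
      state = (code >> 4) & 3u;
      --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = score, _["ops"] = ops);
}
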