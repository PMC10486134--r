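#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Banded global alignment with affine gaps (Gotoh three-state DP).
// Band constraint: |j - i| <= band_width, which connects the DP corners
// whenever band_width >= |n - m| (checked by the R wrapper).
// Gap of length k scores gap_open + (k - 1) * gap_extend.
// Traceback ties resolved diagonal > up (gap in query) > left (gap in ref),
// so output is deterministic for fixed inputs and parameters.

static const double NEG_INF = -1e18;

// state codes: 0 = M (diagonal), 1 = X (up, consumes ref), 2 = Y (left, consumes qry)

// [[Rcpp::export(name = ".banded_align_cpp")]]
List banded_align_cpp(std::string ref, std::string qry,
                      double match, double mismatch,
                      double gap_open, double gap_extend,
                      int band_width) {
  const int n = (int)ref.size();
  const int m = (int)qry.size();
  const int W = band_width;
  const int bw = 2 * W + 1;  // band columns stored per row, offset j - i + W

  // scores for current and previous row, per state
  std::vector<double> Mc(bw), Xc(bw), Yc(bw), Mp(bw), Xp(bw), Yp(bw);
  // packed traceback: 2 bits per state
  std::vector<unsigned char> tb((size_t)(n + 1) * bw, 0);

  auto inband = [&](int i, int j) {
    return j >= 0 && j <= m && j - i >= -W && j - i <= W;
  };

  // row 0
  for (int b = 0; b < bw; ++b) { Mp[b] = Xp[b] = Yp[b] = NEG_INF; }
  Mp[W] = 0.0;  // (0,0)
  for (int j = 1; j <= m && j <= W; ++j) {
    int b = j + W;  // i = 0
    Yp[b] = gap_open + (j - 1) * gap_extend;
    tb[b] = (unsigned char)(2 << 4);  // Y from Y
  }

  for (int i = 1; i <= n; ++i) {
    for (int b = 0; b < bw; ++b) { Mc[b] = Xc[b] = Yc[b] = NEG_INF; }
    int jlo = std::max(0, i - W), jhi = std::min(m, i + W);
    for (int j = jlo; j <= jhi; ++j) {
      int b = j - i + W;          // this row's band index for column j
      unsigned char code = 0;
      if (j == 0) {
        // only vertical moves
        double fromM = (i == 1) ? gap_open : NEG_INF;
        double ext   = (inband(i - 1, 0)) ? Xp[0 - (i - 1) + W] + gap_extend : NEG_INF;
        if (i == 1) { Xc[b] = fromM; code |= (0 << 2); }
        if (ext > Xc[b]) { Xc[b] = ext; code = (unsigned char)((code & ~0x0C) | (1 << 2)); }
        tb[(size_t)i * bw + b] = code;
        continue;
      }
      // M: from (i-1, j-1); band index in previous row is (j-1)-(i-1)+W = b
      double dM = Mp[b], dX = Xp[b], dY = Yp[b];
      double best = dM; int bs = 0;
      if (dX > best) { best = dX; bs = 1; }
      if (dY > best) { best = dY; bs = 2; }
      if (best > NEG_INF / 2) {
        double s = (ref[i - 1] == qry[j - 1]) ? match : mismatch;
        Mc[b] = best + s;
        code |= (unsigned char)bs;
      }
      // X: from (i-1, j); previous-row band index j-(i-1)+W = b+1
      if (b + 1 < bw) {
        double oM = Mp[b + 1] + gap_open;
        double oX = Xp[b + 1] + gap_extend;
        double oY = Yp[b + 1] + gap_open;
        double bx = oM; int xs = 0;
        if (oX > bx) { bx = oX; xs = 1; }
        if (oY > bx) { bx = oY; xs = 2; }
        if (bx > NEG_INF / 2) { Xc[b] = bx; code |= (unsigned char)(xs << 2); }
      }
      // Y: from (i, j-1); same row, band index b-1
      if (b - 1 >= 0) {
        double oM = Mc[b - 1] + gap_open;
        double oX = Xc[b - 1] + gap_open;
        double oY = Yc[b - 1] + gap_extend;
        double by = oM; int ys = 0;
        if (oX > by) { by = oX; ys = 1; }
        if (oY > by) { by = oY; ys = 2; }
        if (by > NEG_INF / 2) { Yc[b] = by; code |= (unsigned char)(ys << 4); }
      }
      tb[(size_t)i * bw + b] = code;
    }
    std::swap(Mc, Mp); std::swap(Xc, Xp); std::swap(Yc, Yp);
  }

  int bEnd = m - n + W;
  if (bEnd < 0 || bEnd >= bw)
    stop("band too narrow to connect alignment corners; widen band_width");
  double sM = Mp[bEnd], sX = Xp[bEnd], sY = Yp[bEnd];
  double score = sM; int state = 0;
  if (sX > score) { score = sX; state = 1; }
  if (sY > score) { score = sY; state = 2; }
  if (score < NEG_INF / 2)
    stop("band too narrow to connect alignment corners; widen band_width");

  // traceback
  std::string ar, aq;
  ar.reserve(n + m); aq.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char code = tb[(size_t)i * bw + (j - i + W)];
    int prev;
    if (state == 0) {
      prev = code & 0x03;
      ar.push_back(ref[i - 1]); aq.push_back(qry[j - 1]);
      --i; --j;
    } else if (state == 1) {
      prev = (code >> 2) & 0x03;
      ar.push_back(ref[i - 1]); aq.push_back('-');
      --i;
    } else {
      prev = (code >> 4) & 0x03;
      ar.push_back('-'); aq.push_back(qry[j - 1]);
      --j;
    }
    state = prev;
  }
  std::reverse(ar.begin(), ar.end());
  std::reverse(aq.begin(), aq.end());

  return List::create(_["aligned_ref"] = ar, _["aligned_qry"] = aq,
                      _["score"] = score);
}
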