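#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>

using namespace Rcpp;

// Banded local (Smith-Waterman/Gotoh) extension around a seed diagonal.
//
// The DP explores query positions [0, qlen) against reference positions
// [rlo, rhi) where the window is capped around the seed anchor, and only
// cells within `band` diagonals of the seed diagonal d0 = rpos - qpos are
// considered.  Affine gaps: the first gapped column costs `gap_open`, each
// further column `gap_extend`.  Returns the best-scoring local alignment in
// the window as 0-based half-open intervals plus a run-length M/X/I/D cigar
// (I consumes query, D consumes reference).

static const int NEG_INF = INT_MIN / 4;

// [[Rcpp::export]]
List banded_extend_cpp(const std::string& q, const std::string& r,
                       int qpos, int rpos,
                       int match, int mismatch, int gap_open, int gap_extend,
                       int window, int band) {
  const int qlen = (int)q.size();
  const int rlen = (int)r.size();
  if (qlen == 0 || rlen == 0) return List::create(_["score"] = 0);
  if (qpos < 0 || qpos >= qlen || rpos < 0 || rpos >= rlen)
    stop("seed anchor outside sequence bounds");

  const int rlo = std::max(0, rpos - window);
  const int rhi = std::min(rlen, rpos + window);
  const int d0 = rpos - qpos;
  const int bw = 2 * band + 1;

  // offset within band for cell (i, j): (j - i - d0) + band
  std::vector<int> H((size_t)qlen * bw, NEG_INF);
  std::vector<int> E((size_t)qlen * bw, NEG_INF);
  std::vector<int> F((size_t)qlen * bw, NEG_INF);
  std::vector<signed char> tH((size_t)qlen * bw, 0);
  std::vector<signed char> tE((size_t)qlen * bw, 0);
  std::vector<signed char> tF((size_t)qlen * bw, 0);

  int best = 0, bi = -1, bj = -1;

  for (int i = 0; i < qlen; ++i) {
    const int jmin = std::max(rlo, i + d0 - band);
    const int jmax = std::min(rhi - 1, i + d0 + band);
    for (int j = jmin; j <= jmax; ++j) {
      const int off = (j - i - d0) + band;
      const size_t idx = (size_t)i * bw + off;

      // E: gap consuming reference ('D'); predecessor (i, j-1), offset-1
      int e = NEG_INF; signed char te = 0;
      if (off - 1 >= 0 && j - 1 >= rlo) {
        const size_t pidx = (size_t)i * bw + (off - 1);
        const int open_sc = (H[pidx] > NEG_INF) ? H[pidx] + gap_open : NEG_INF;
        const int ext_sc  = (E[pidx] > NEG_INF) ? E[pidx] + gap_extend : NEG_INF;
        if (open_sc >= ext_sc) { e = open_sc; te = 1; } else { e = ext_sc; te = 0; }
      }
      E[idx] = e; tE[idx] = te;

      // F: gap consuming query ('I'); predecessor (i-1, j), offset+1
      int f = NEG_INF; signed char tf = 0;
      if (off + 1 < bw && i - 1 >= 0) {
        const size_t pidx = (size_t)(i - 1) * bw + (off + 1);
        const int open_sc = (H[pidx] > NEG_INF) ? H[pidx] + gap_open : NEG_INF;
        const int ext_sc  = (F[pidx] > NEG_INF) ? F[pidx] + gap_extend : NEG_INF;
        if (open_sc >= ext_sc) { f = open_sc; tf = 1; } else { f = ext_sc; tf = 0; }
      }
      F[idx] = f; tF[idx] = tf;

      // H: local optimum ending with q[i] ~ r[j]
      const char qc = q[(size_t)i], rc = r[(size_t)j];
      const int s = (qc == rc && qc != 'N') ? match : mismatch;
      int hdiag = 0;  // local start
      if (i - 1 >= 0 && j - 1 >= rlo) {
        const size_t pidx = (size_t)(i - 1) * bw + off;  // same offset
        if (H[pidx] > 0) hdiag = H[pidx];
      }
      int h = hdiag + s; signed char th = 1;
      if (e > h) { h = e; th = 2; }
      if (f > h) { h = f; th = 3; }
      if (h <= 0) { h = 0; th = 0; }
      H[idx] = h; tH[idx] = th;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  if (best <= 0) return List::create(_["score"] = 0);

  // traceback
  std::string ops;  // reversed per-column ops
  int i = bi, j = bj, minI = bi, minJ = bj;
  char state = 'H';
  while (true) {
    const int off = (j - i - d0) + band;
    const size_t idx = (size_t)i * bw + off;
    if (state == 'H') {
      const signed char t = tH[idx];
      if (t == 0) break;
      if (t == 1) {
        const char qc = q[(size_t)i], rc = r[(size_t)j];
        ops.push_back((qc == rc && qc != 'N') ? 'M' : 'X');
        minI = i; minJ = j;
        --i; --j;
        if (i < 0 || j < rlo) break;
      } else if (t == 2) {
        state = 'E';
      } else {
        state = 'F';
      }
    } else if (state == 'E') {
      const signed char t = tE[idx];
      ops.push_back('D');
      minJ = j;
      --j;
      if (t == 1) state = 'H';
      if (j < rlo) break;
    } else {  // F
      const signed char t = tF[idx];
      ops.push_back('I');
      minI = i;
      --i;
      if (t == 1) state = 'H';
      if (i < 0) break;
    }
  }

  // run-length encode reversed ops (reverse first)
  std::string cigar;
  const int n = (int)ops.size();
  int k = n - 1;
  while (k >= 0) {
    const char op = ops[(size_t)k];
    int run = 0;
    while (k >= 0 && ops[(size_t)k] == op) { ++run; --k; }
    cigar += std::to_string(run);
    cigar.push_back(op);
  }

  return List::create(
    _["score"] = best,
    _["qstart"] = minI, _["qend"] = bi + 1,
    _["rstart"] = minJ, _["rend"] = bj + 1,
    _["cigar"] = cigar);
}
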