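#include <Rcpp.h>
#include <cstdint>
#include <climits>
#include <vector>
#include <string>

using namespace Rcpp;

// Three-state affine-gap DP (Gotoh). Scores are pre-scaled integers (x2 in R
// so that half-point gap-extend penalties stay exact).
//
// Gap convention: a gap of length L costs open + (L-1) * ext.
//
// Modes: 0 = global (Needleman-Wunsch), 1 = local (Smith-Waterman),
// 2 = semiglobal/overlap: alignment may start on the top row or left column
// and end on the bottom row or right column, so leading/trailing gaps on
// either sequence are free at the ends of the other; for read-vs-reference
// use this clips the read only at reference ends.
//
// Banding restricts cells to |j - i - diag| <= band (meaningful for mode 2
// with a seeded diagonal; band < 0 disables).
//
// Traceback tie-break, fixed: diagonal (match/mismatch) preferred over gaps,
// deletions (gap in query) preferred over insertions.
//
// Score rows are padded with a NEG sentinel on both ends so predecessor
// reads outside the previous row's band need no bounds checks; NEG is large
// enough in magnitude to dominate yet never overflow when a penalty is
// added to it.

static const int NEG = INT_MIN / 4;

// packed traceback codes per state, 2 bits each
// M: 0=fromM 1=fromY 2=fromX 3=path start
// X: 0=fromM 1=fromX 2=fromY
// Y: 0=fromM 1=fromY 2=fromX

// [[Rcpp::export]]
List gotoh_cpp(std::string a, std::string b,
               int match2, int mismatch2, int open2, int ext2,
               int mode, long band, long diag) {
  const long m = (long)a.size(), n = (long)b.size();
  if (m == 0 || n == 0) stop("empty sequence");

  bool banded = band >= 0;
  if (!banded) { band = m + n + 1; diag = 0; }
  const long W = std::min(n, 2 * band) + 1;

  std::vector<long> jlo(m + 1), jhi(m + 1);
  for (long i = 0; i <= m; ++i) {
    jlo[i] = std::max(0L, i + diag - band);
    jhi[i] = std::min(n, i + diag + band);
    if (jlo[i] > n) jlo[i] = n + 1; // empty row range
  }
  if (banded && jlo[0] > 0 && mode != 2)
    stop("band excludes origin for non-semiglobal mode");

  // rows padded: index (j - rowlo + 1), sentinels at both ends
  std::vector<int> Mprev(W + 2, NEG), Xprev(W + 2, NEG), Yprev(W + 2, NEG);
  std::vector<int> Mcur(W + 2, NEG), Xcur(W + 2, NEG), Ycur(W + 2, NEG);
  std::vector<uint8_t> tb((size_t)(m + 1) * W, 0);

  // row 0
  {
    const long lo = jlo[0], hi = jhi[0];
    for (long j = lo; j <= hi; ++j) {
      long c = j - lo + 1;
      uint8_t ty = 0;
      if (j == 0) { Mprev[c] = 0; }
      else if (mode == 0) {
        Yprev[c] = open2 + (int)(j - 1) * ext2;
        ty = (j == 1) ? 0 : 1;
      } else { // local / overlap: free start along the top row
        Mprev[c] = 0;
      }
      tb[j - lo] = (uint8_t)(3u | ((unsigned)ty << 4));
    }
  }

  long bestScore = NEG;
  long bestI = -1, bestJ = -1; int bestState = 0; // 0=M 1=Y 2=X
  bool anyCell = jlo[0] <= jhi[0];

  if (mode == 1) { // local: the empty alignment is admissible
    bestScore = 0; bestI = 0; bestJ = jlo[0] <= 0 ? 0 : jlo[0]; bestState = 0;
  }

  const char *A = a.c_str(), *B = b.c_str();

  for (long i = 1; i <= m; ++i) {
    const long lo = jlo[i], hi = jhi[i];
    std::fill(Mcur.begin(), Mcur.end(), NEG);
    std::fill(Xcur.begin(), Xcur.end(), NEG);
    std::fill(Ycur.begin(), Ycur.end(), NEG);
    if (lo > hi) { std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur); continue; }
    anyCell = true;
    const char ai = A[i - 1];
    const bool aiN = (ai == 'N' || ai == 'n');
    const long loP = jlo[i - 1];
    uint8_t *tbrow = &tb[(size_t)i * W];
    // pointers shifted so that indexing by j is direct
    const int *MP = Mprev.data() + 1 - loP;
    const int *XP = Xprev.data() + 1 - loP;
    const int *YP = Yprev.data() + 1 - loP;
    int *MC = Mcur.data() + 1 - lo;
    int *XC = Xcur.data() + 1 - lo;
    int *YC = Ycur.data() + 1 - lo;

    long j = lo;
    if (j == 0) { // left column cell
      uint8_t tm = 0, tx = 0;
      if (mode == 0) {
        XC[0] = open2 + (int)(i - 1) * ext2;
        tx = (i == 1) ? 0 : 1;
      } else {
        MC[0] = 0; tm = 3; // free start down the left column
      }
      tbrow[0 - lo] = (uint8_t)((unsigned)tm | ((unsigned)tx << 2));
      ++j;
    }
    for (; j <= hi; ++j) {
      // M: diagonal predecessor (i-1, j-1)
      const int pm = MP[j - 1], px = XP[j - 1], py = YP[j - 1];
      int bestDiag = pm; uint8_t tm = 0;
      if (py > bestDiag) { bestDiag = py; tm = 1; }
      if (px > bestDiag) { bestDiag = px; tm = 2; }
      const char bj = B[j - 1];
      int Mv = bestDiag + ((ai == bj && !aiN) ? match2 : mismatch2);
      if (mode == 1 && Mv < 0) { Mv = 0; tm = 3; }

      // X: gap in target, consumes query; predecessor (i-1, j)
      const int qm = MP[j], qx = XP[j], qy = YP[j];
      int Xv = qm + open2; uint8_t tx = 0;
      if (qx + ext2 > Xv) { Xv = qx + ext2; tx = 1; }
      if (qy + open2 > Xv) { Xv = qy + open2; tx = 2; }

      // Y: gap in query, consumes target; predecessor (i, j-1)
      const int lm = MC[j - 1], ly = YC[j - 1], lx = XC[j - 1];
      int Yv = lm + open2; uint8_t ty = 0;
      if (ly + ext2 > Yv) { Yv = ly + ext2; ty = 1; }
      if (lx + open2 > Yv) { Yv = lx + open2; ty = 2; }

      MC[j] = Mv; XC[j] = Xv; YC[j] = Yv;
      tbrow[j - lo] =
        (uint8_t)((unsigned)tm | ((unsigned)tx << 2) | ((unsigned)ty << 4));

      if (mode == 1 && Mv > bestScore) {
        bestScore = Mv; bestI = i; bestJ = j; bestState = 0;
      }
    }
    if (mode == 2) {
      if (i == m) { // free end along the bottom row
        for (long jj = lo; jj <= hi; ++jj) {
          int v = MC[jj]; int st = 0;
          if (YC[jj] > v) { v = YC[jj]; st = 1; }
          if (XC[jj] > v) { v = XC[jj]; st = 2; }
          if (v > bestScore || (v == bestScore && (i + jj) > (bestI + bestJ))) {
            bestScore = v; bestI = i; bestJ = jj; bestState = st;
          }
        }
      } else if (n >= lo && n <= hi) { // free end down the right column
        int v = MC[n]; int st = 0;
        if (YC[n] > v) { v = YC[n]; st = 1; }
        if (XC[n] > v) { v = XC[n]; st = 2; }
        if (v > bestScore || (v == bestScore && (i + n) > (bestI + bestJ))) {
          bestScore = v; bestI = i; bestJ = n; bestState = st;
        }
      }
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  if (mode == 0) {
    if (n >= jlo[m] && n <= jhi[m]) {
      long c = n - jlo[m] + 1;
      bestScore = Mprev[c]; bestState = 0;
      if (Yprev[c] > bestScore) { bestScore = Yprev[c]; bestState = 1; }
      if (Xprev[c] > bestScore) { bestScore = Xprev[c]; bestState = 2; }
      bestI = m; bestJ = n;
    }
  }

  if (!anyCell || bestI < 0 || bestScore <= NEG / 2) {
    return List::create(_["ok"] = false);
  }

  std::vector<char> opsRev;
  long i = bestI, j = bestJ; int st = bestState;
  long nmatch = 0;
  if (mode == 1 && bestScore == 0) { // empty local alignment
    return List::create(
      _["ok"] = true, _["score2"] = 0,
      _["op"] = CharacterVector(0), _["len"] = IntegerVector(0),
      _["q0"] = 0L, _["q1"] = 0L, _["t0"] = 0L, _["t1"] = 0L,
      _["nmatch"] = 0L, _["ncols"] = 0L);
  }
  while (!(i == 0 && j == 0)) {
    uint8_t code = tb[(size_t)i * W + (j - jlo[i])];
    if (st == 0) {
      uint8_t tm = code & 3u;
      if (tm == 3) break; // free path start (local / overlap boundary)
      char qc = a[i - 1], tc = b[j - 1];
      bool isM = (qc == tc && qc != 'N' && qc != 'n');
      opsRev.push_back(isM ? 'M' : 'S'); // S renamed to X (mismatch) below
      if (isM) ++nmatch;
      --i; --j;
      st = (tm == 0) ? 0 : (tm == 1 ? 1 : 2);
    } else if (st == 2) { // X: consumes query
      uint8_t tx = (code >> 2) & 3u;
      opsRev.push_back('I');
      --i;
      st = (tx == 0) ? 0 : (tx == 1 ? 2 : 1);
    } else { // Y: consumes target
      uint8_t ty = (code >> 4) & 3u;
      opsRev.push_back('D');
      --j;
      st = (ty == 0) ? 0 : (ty == 1 ? 1 : 2);
    }
  }

  long q0 = i, t0 = j, q1 = bestI, t1 = bestJ;

  // run-length encode (reversed walk -> forward order)
  std::vector<char> opc; std::vector<int> opl;
  for (long k = (long)opsRev.size() - 1; k >= 0; --k) {
    char o = opsRev[k];
    if (o == 'S') o = 'X';
    if (!opc.empty() && opc.back() == o) opl.back()++;
    else { opc.push_back(o); opl.push_back(1); }
  }
  long ncols = 0;
  for (size_t k = 0; k < opl.size(); ++k) ncols += opl[k];
  CharacterVector opOut(opc.size());
  IntegerVector lenOut(opl.size());
  for (size_t k = 0; k < opc.size(); ++k) {
    opOut[k] = std::string(1, opc[k]);
    lenOut[k] = opl[k];
  }

  return List::create(
    _["ok"] = true, _["score2"] = (double)bestScore,
    _["op"] = opOut, _["len"] = lenOut,
    _["q0"] = (double)q0, _["q1"] = (double)q1,
    _["t0"] = (double)t0, _["t1"] = (double)t1,
    _["nmatch"] = (double)nmatch, _["ncols"] = (double)ncols);
}

// [[Rcpp::export]]
std::string revcomp_cpp(std::string s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    char c = s[s.size() - 1 - i], r;
    switch (c) {
      case 'A': r = 'T'; break; case 'C': r = 'G'; break;
      case 'G': r = 'C'; break; case 'T': r = 'A'; break;
      case 'a': r = 't'; break; case 'c': r = 'g'; break;
      case 'g': r = 'c'; break; case 't': r = 'a'; break;
      default: r = 'N';
    }
    out[i] = r;
  }
  return out;
}

// integer codes of all k-mers (base-4, A=0 C=1 G=2 T=3); -1 where the window
// contains a non-ACGT character. k must be <= 15.
// [[Rcpp::export]]
IntegerVector kmer_codes_cpp(std::string s, int k) {
  long n = (long)s.size();
  if (k < 1 || k > 15) stop("k must be in 1..15");
  if (n < k) return IntegerVector(0);
  IntegerVector out(n - k + 1);
  long code = 0, bad = 0; // bad = count of invalid chars in current window
  const long mask = (1L << (2 * k)) - 1;
  for (long i = 0; i < n; ++i) {
    int v;
    switch (s[i]) {
      case 'A': case 'a': v = 0; break;
      case 'C': case 'c': v = 1; break;
      case 'G': case 'g': v = 2; break;
      case 'T': case 't': v = 3; break;
      default: v = -1;
    }
    code = ((code << 2) | (v < 0 ? 0 : v)) & mask;
    if (v < 0) bad = k; else if (bad > 0) --bad;
    if (i >= k - 1) out[i - k + 1] = (bad > 0) ? -1 : (int)code;
  }
  return out;
}
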