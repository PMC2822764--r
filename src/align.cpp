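#include <Rcpp.h>
#include <vector>
#include <array>
#include <cstring>
using namespace Rcpp;

// Waterman-Eggert style multi-HSP local alignment of an integer-coded
// protein query against one integer-coded translated frame, affine gaps.
// After each reported alignment the subject residues it used are masked
// (never the query: one query legitimately hits several tandem copies)
// and the DP is re-run, until the best raw score drops below minRaw.
//
// DP keeps only rolling score rows plus a packed per-cell direction
// byte for traceback:
//   bits 0-1: origin of H (0 stop, 1 diagonal, 2 from E, 3 from F)
//   bit 2: E extended from E[i][j-1] (else opened from H[i][j-1])
//   bit 3: F extended from F[i-1][j] (else opened from H[i-1][j])

namespace {

const int NEG = -1000000;

struct Hsp {
  int qs, qe, ss, se, raw;
};

bool onePass(const std::vector<int> &q, const std::vector<int> &sK,
             const int *mat, int K, int go, int ge, int minRaw,
             Hsp &out, std::vector<unsigned char> &dir,
             std::vector<int> &Hrow, std::vector<int> &Hprev,
             std::vector<int> &Fcol) {
  const int m = (int)q.size(), n = (int)sK.size();
  const int goe = go + ge;
  std::fill(Hprev.begin(), Hprev.end(), 0);
  std::fill(Fcol.begin(), Fcol.end(), NEG);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const int *matRow = mat + q[i - 1];
    unsigned char *drow = &dir[(size_t)(i - 1) * n];
    Hrow[0] = 0;
    int e = NEG;
    int hdiag = Hprev[0];  // Hprev[j-1], carried
    int hleft = 0;         // Hrow[j-1], carried
    for (int j = 1; j <= n; ++j) {
      const int eOpen = hleft - goe, eExt = e - ge;
      const bool ex = eExt > eOpen;
      e = ex ? eExt : eOpen;
      const int hup = Hprev[j];
      const int fOpen = hup - goe, fExt = Fcol[j] - ge;
      const bool fx = fExt > fOpen;
      const int f = fx ? fExt : fOpen;
      Fcol[j] = f;
      const int dg = hdiag + matRow[sK[j - 1]];
      hdiag = hup;
      int h = dg;
      unsigned char o = 1;
      if (e > h) { h = e; o = 2; }
      if (f > h) { h = f; o = 3; }
      if (h <= 0) { h = 0; o = 0; }
      hleft = h;
      Hrow[j] = h;
      drow[j - 1] = (unsigned char)(o | (ex ? 4 : 0) | (fx ? 8 : 0));
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hrow, Hprev);
  }
  if (best < minRaw || best <= 0) return false;

  int i = bi, j = bj;
  int state = 0;  // 0 = H, 1 = E, 2 = F
  for (;;) {
    if (i <= 0 || j <= 0) break;
    const unsigned char d = dir[(size_t)(i - 1) * n + (j - 1)];
    if (state == 0) {
      const int o = d & 3;
      if (o == 0) break;            // score 0: local start
      if (o == 1) { --i; --j; }
      else if (o == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      if (d & 4) { --j; }           // extend gap
      else { --j; state = 0; }      // gap opened from H[i][j-1]
    } else {
      if (d & 8) { --i; }
      else { --i; state = 0; }
    }
  }
  out.qs = i + 1; out.qe = bi;
  out.ss = j + 1; out.se = bj;
  out.raw = best;
  return true;
}

}  // namespace

// Six-frame translated search: dna is 0-3 coded (negative = ambiguous),
// codonAa maps codon index 16*b1+4*b2+b3 to a matrix-alphabet code,
// xCode is the code for X (ambiguous residue). Runs the Waterman-Eggert
// search on every frame of both strands and returns one row per HSP:
// strand (0 plus, 1 minus), frame, qstart, qend, sstart, send (aa
// coordinates within the frame, 1-based), raw.

// [[Rcpp::export]]
IntegerMatrix cpp_search_frames(IntegerVector q, IntegerVector dna,
                                IntegerVector codonAa, int xCode,
                                IntegerMatrix mat, int gapOpen,
                                int gapExt, int minRaw, int maxHsps) {
  const int m = q.size(), n = dna.size();
  if (m == 0 || n < 3) return IntegerMatrix(0, 7);
  const int K = mat.nrow();
  std::vector<int> matv((size_t)K * (K + 1));
  for (int b = 0; b < K; ++b)
    for (int a = 0; a < K; ++a) matv[(size_t)b * K + a] = mat(a, b);
  for (int a = 0; a < K; ++a) matv[(size_t)K * K + a] = -1000;
  std::vector<int> qv(q.begin(), q.end());

  std::vector<int> fwd(dna.begin(), dna.end()), rev(n);
  for (int i = 0; i < n; ++i) {
    const int b = dna[n - 1 - i];
    rev[i] = b < 0 ? -1 : 3 - b;
  }

  std::vector<int> sK;
  std::vector<unsigned char> dir;
  std::vector<int> Hrow, Hprev, Fcol;
  if (minRaw < 1) minRaw = 1;
  std::vector<std::array<int, 7>> rows;

  for (int strand = 0; strand < 2; ++strand) {
    const std::vector<int> &s = strand == 0 ? fwd : rev;
    for (int f = 0; f < 3; ++f) {
      const int na = (n - f) / 3;
      if (na < 1) continue;
      sK.assign(na, 0);
      for (int a = 0; a < na; ++a) {
        const int b1 = s[f + 3 * a], b2 = s[f + 3 * a + 1],
                  b3 = s[f + 3 * a + 2];
        int code = (b1 < 0 || b2 < 0 || b3 < 0)
          ? xCode : codonAa[16 * b1 + 4 * b2 + b3];
        sK[a] = code * K;
      }
      dir.assign((size_t)m * na, 0);
      Hrow.assign(na + 1, 0); Hprev.assign(na + 1, 0);
      Fcol.assign(na + 1, 0);
      for (int iter = 0; iter < maxHsps; ++iter) {
        Hsp h;
        if (!onePass(qv, sK, matv.data(), K, gapOpen, gapExt, minRaw,
                     h, dir, Hrow, Hprev, Fcol))
          break;
        rows.push_back({strand, f, h.qs, h.qe, h.ss, h.se, h.raw});
        for (int j = h.ss - 1; j < h.se; ++j) sK[j] = K * K;
      }
    }
  }
  IntegerMatrix out((int)rows.size(), 7);
  for (int r = 0; r < (int)rows.size(); ++r)
    for (int c = 0; c < 7; ++c) out(r, c) = rows[r][c];
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_local_hsps(IntegerVector q, IntegerVector s,
                             IntegerMatrix mat, int gapOpen, int gapExt,
                             int minRaw, int maxHsps) {
  const int m = q.size(), n = s.size();
  if (m == 0 || n == 0) return IntegerMatrix(0, 5);
  const int K = mat.nrow();
  // matrix extended with one mask column scoring NEG-ish vs everything
  std::vector<int> matv((size_t)K * (K + 1));
  for (int b = 0; b < K; ++b)
    for (int a = 0; a < K; ++a) matv[(size_t)b * K + a] = mat(a, b);
  for (int a = 0; a < K; ++a) matv[(size_t)K * K + a] = -1000;
  std::vector<int> qv(q.begin(), q.end());
  std::vector<int> sK(n);
  for (int j = 0; j < n; ++j)
    sK[j] = (s[j] < 0 || s[j] >= K ? K : s[j]) * K;

  std::vector<unsigned char> dir((size_t)m * n);
  std::vector<int> Hrow(n + 1), Hprev(n + 1), Fcol(n + 1);

  std::vector<Hsp> hits;
  if (minRaw < 1) minRaw = 1;
  for (int iter = 0; iter < maxHsps; ++iter) {
    Hsp h;
    if (!onePass(qv, sK, matv.data(), K, gapOpen, gapExt, minRaw, h,
                 dir, Hrow, Hprev, Fcol))
      break;
    hits.push_back(h);
    for (int j = h.ss - 1; j < h.se; ++j) sK[j] = K * K;
  }
  IntegerMatrix out((int)hits.size(), 5);
  for (int r = 0; r < (int)hits.size(); ++r) {
    out(r, 0) = hits[r].qs; out(r, 1) = hits[r].qe;
    out(r, 2) = hits[r].ss; out(r, 3) = hits[r].se;
    out(r, 4) = hits[r].raw;
  }
  return out;
}
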