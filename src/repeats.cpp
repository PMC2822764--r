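#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Fast scan for candidate tandem-repeat unit sizes: for each lag u the
// score is the length of the longest run of positions with s[i] == s[i+u]
// (negative codes, e.g. N, never match). One row per unit with its best
// run: unit, score, start, end (1-based span covering both repeat halves).

// [[Rcpp::export]]
IntegerMatrix cpp_quick_tandem(IntegerVector s, int maxUnit) {
  const int n = s.size();
  std::vector<int> unit, score, start, end;
  for (int u = 1; u <= maxUnit && 2 * u <= n; ++u) {
    int run = 0, best = 0, bestEnd = -1;
    for (int i = 0; i + u < n; ++i) {
      if (s[i] >= 0 && s[i] == s[i + u]) {
        ++run;
        if (run > best) { best = run; bestEnd = i; }
      } else run = 0;
    }
    if (best > 0) {
      unit.push_back(u);
      score.push_back(best);
      start.push_back(bestEnd - best + 2);   // 1-based first position of run
      end.push_back(bestEnd + u + 1);        // 1-based last position covered
    }
  }
  IntegerMatrix out((int)unit.size(), 4);
  for (int r = 0; r < (int)unit.size(); ++r) {
    out(r, 0) = unit[r]; out(r, 1) = score[r];
    out(r, 2) = start[r]; out(r, 3) = end[r];
  }
  return out;
}

// Exact tandem-repeat search over the given unit sizes (ascending).
// A repeat block is `copies` consecutive whole copies of length `unit`
// starting at `start`; its consensus takes the majority symbol per
// column and the score is (#matches to consensus) - (#mismatches)
// = 2 * sum(column majorities) - copies * unit. Ties broken toward the
// smaller unit, then the leftmost start. Returns (unit, start, copies,
// score), all zero when nothing scores > 0.

// [[Rcpp::export]]
IntegerVector cpp_exact_tandem(IntegerVector s, IntegerVector units) {
  const int n = s.size();
  int nsym = 1;
  for (int i = 0; i < n; ++i) if (s[i] + 1 > nsym) nsym = s[i] + 1;
  int bu = 0, bstart = 0, bcopies = 0, bscore = 0;
  for (int ui = 0; ui < units.size(); ++ui) {
    const int u = units[ui];
    if (u < 1 || 2 * u > n) continue;
    std::vector<int> cnt((size_t)u * nsym);
    std::vector<int> colmax(u);
    for (int a = 0; a < u; ++a) {
      const int k = (n - a) / u;
      if (k < 2) continue;
      for (int i = 0; i + 1 < k; ++i) {
        std::fill(cnt.begin(), cnt.end(), 0);
        std::fill(colmax.begin(), colmax.end(), 0);
        int summax = 0;
        for (int j = i; j < k; ++j) {
          const int off = a + j * u;
          for (int c = 0; c < u; ++c) {
            const int b = s[off + c];
            if (b < 0) continue;  // N: counted as mismatch to any consensus
            const int cc = ++cnt[(size_t)c * nsym + b];
            if (cc > colmax[c]) { summax += cc - colmax[c]; colmax[c] = cc; }
          }
          const int copies = j - i + 1;
          if (copies >= 2) {
            const int sc = 2 * summax - copies * u;
            const int st = a + i * u + 1;
            if (sc > bscore ||
                (sc == bscore && sc > 0 &&
                 (u < bu || (u == bu && st < bstart)))) {
              bscore = sc; bu = u; bstart = st; bcopies = copies;
            }
          }
        }
      }
    }
  }
  return IntegerVector::create(bu, bstart, bcopies, bscore);
}

// Dotplot with sliding-window identity: a dot sits at centre (i, j) when
// the `window`-long windows centred there (window odd, fully inside both
// sequences) share >= `stringency` identical symbols. Consecutive dots on
// one diagonal are merged into runs; one row per run:
// a_start, a_end, b_start, b_end, length (1-based centre coordinates).

// [[Rcpp::export]]
IntegerMatrix cpp_dotplot(IntegerVector a, IntegerVector b, int window,
                          int stringency) {
  const int na = a.size(), nb = b.size();
  const int half = window / 2;
  std::vector<int> as, ae, bs, be, ln;
  std::vector<int> match;
  for (int d = -(na - 1); d <= nb - 1; ++d) {
    const int i0 = d < 0 ? -d : 0;
    const int j0 = i0 + d;
    const int L = std::min(na - i0, nb - j0);
    if (L < window) continue;
    match.assign(L + 1, 0);
    for (int t = 0; t < L; ++t)
      match[t + 1] = match[t] +
        (a[i0 + t] >= 0 && a[i0 + t] == b[j0 + t] ? 1 : 0);
    int runStart = -1, prev = -2;
    for (int t = half; t < L - half; ++t) {
      const int ident = match[t + half + 1] - match[t - half];
      if (ident >= stringency) {
        if (t != prev + 1) {
          if (runStart >= 0) {
            as.push_back(i0 + runStart + 1); ae.push_back(i0 + prev + 1);
            bs.push_back(j0 + runStart + 1); be.push_back(j0 + prev + 1);
            ln.push_back(prev - runStart + 1);
          }
          runStart = t;
        }
        prev = t;
      }
    }
    if (runStart >= 0) {
      as.push_back(i0 + runStart + 1); ae.push_back(i0 + prev + 1);
      bs.push_back(j0 + runStart + 1); be.push_back(j0 + prev + 1);
      ln.push_back(prev - runStart + 1);
    }
  }
  IntegerMatrix out((int)as.size(), 5);
  for (int r = 0; r < (int)as.size(); ++r) {
    out(r, 0) = as[r]; out(r, 1) = ae[r];
    out(r, 2) = bs[r]; out(r, 3) = be[r]; out(r, 4) = ln[r];
  }
  return out;
}
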