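#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

// Unit scoring: match +1, mismatch -1, gap open -1 plus -1 per gapped
// base (a gap of length L costs 1 + L).  An exact overlap of L bases
// scores exactly L, and optimal local scores on unrelated sequence stay
// in the logarithmic regime (tens even for 30 kb windows; per-base-only
// gap costs would be in the linear phase and produce spurious
// multi-thousand chains).  Ambiguity codes never match (N-N counts as a
// mismatch).

static inline int enc(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

// Banded affine Smith-Waterman over diagonals d = j - i in [dlo, dhi];
// the full dynamic program is the special case dlo = -n, dhi = m.
// Traceback bytes per cell:
//   bits 0-1: H origin (0 stop, 1 diag, 2 from E (gap consuming b),
//             3 from F (gap consuming a))
//   bit 2:    E opened here (1) vs extended (0)
//   bit 3:    F opened here (1) vs extended (0)
// [[Rcpp::export]]
List sw_banded_cpp(std::string a, std::string b, int dlo, int dhi) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) return List::create(_["score"] = 0);
  dlo = std::max(dlo, -n);
  dhi = std::min(dhi, m);
  if (dlo > dhi) return List::create(_["score"] = 0);
  const int w = dhi - dlo + 1;
  const int NEG = -1000000000;
  const int GO = 2; // first gapped base: open (1) + extend (1)
  const int GE = 1;

  std::vector<int> ea(n), eb(m);
  for (int i = 0; i < n; ++i) ea[i] = enc(a[i]);
  for (int j = 0; j < m; ++j) eb[j] = enc(b[j]);

  // cell (i, j) of row i lives at band column j - i - dlo
  std::vector<int> Hprev(w, 0), Hcur(w, 0), Ecur(w, NEG);
  // per-column F (vertical gaps): F(i,j) = max(F(i-1,j)-GE, H(i-1,j)-GO)
  std::vector<int> Fcol(m + 1, NEG);
  std::vector<uint8_t> tb((size_t)(n + 1) * w, 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const int jlo = std::max(1, i + dlo), jhi = std::min(m, i + dhi);
    std::fill(Hcur.begin(), Hcur.end(), 0);
    std::fill(Ecur.begin(), Ecur.end(), NEG);
    for (int j = jlo; j <= jhi; ++j) {
      const int col = j - i - dlo;
      // E: horizontal gap (consume b)
      int Eval = NEG; uint8_t eOpen = 0;
      if (col >= 1) {
        const int ext = Ecur[col - 1] - GE;
        const int opn = Hcur[col - 1] - GO;
        if (opn >= ext) { Eval = opn; eOpen = 1; } else Eval = ext;
      }
      // F: vertical gap (consume a); H(i-1, j) sits at prev-row col + 1
      int Fval = NEG; uint8_t fOpen = 0;
      {
        const int ext = Fcol[j] - GE;
        const int opn = (col + 1 < w) ? Hprev[col + 1] - GO : NEG;
        if (opn >= ext) { Fval = opn; fOpen = 1; } else Fval = ext;
      }
      const int s = (ea[i - 1] == eb[j - 1] && ea[i - 1] < 4) ? 1 : -1;
      const int diag = Hprev[col] + s; // H(i-1, j-1) at prev-row col
      int h = 0; uint8_t dir = 0;
      if (diag > h) { h = diag; dir = 1; }
      if (Eval > h) { h = Eval; dir = 2; }
      if (Fval > h) { h = Fval; dir = 3; }
      Hcur[col] = h;
      Ecur[col] = Eval;
      Fcol[j] = Fval;
      tb[(size_t)i * w + col] = (uint8_t)(dir | (eOpen << 2) | (fOpen << 3));
      if (h > best) { best = h; bi = i; bj = j; }
    }
    // columns falling out of the band next row must not chain their F
    const int njlo = std::max(1, (i + 1) + dlo);
    for (int j = jlo; j < njlo && j <= m; ++j) Fcol[j] = NEG;
    std::swap(Hprev, Hcur);
  }

  if (best <= 0) return List::create(_["score"] = 0);

  int i = bi, j = bj;
  int matches = 0, mismatches = 0, gap_opens = 0, gap_bases = 0;
  int ai_start = bi, bj_start = bj;
  int state = 0; // 0 H, 1 E, 2 F
  while (i > 0 && j > 0) {
    const uint8_t t = tb[(size_t)i * w + (j - i - dlo)];
    if (state == 0) {
      const uint8_t dir = t & 3;
      if (dir == 0) break;
      if (dir == 1) {
        if (ea[i - 1] == eb[j - 1] && ea[i - 1] < 4) ++matches;
        else ++mismatches;
        ai_start = i; bj_start = j;
        --i; --j;
      } else if (dir == 2) state = 1;
      else state = 2;
    } else if (state == 1) { // E: consume b
      ++gap_bases;
      if ((t >> 2) & 1) { ++gap_opens; state = 0; }
      --j;
    } else { // F: consume a
      ++gap_bases;
      if ((t >> 3) & 1) { ++gap_opens; state = 0; }
      --i;
    }
  }

  return List::create(
    _["score"] = best,
    _["a_start"] = ai_start, _["a_end"] = bi,
    _["b_start"] = bj_start, _["b_end"] = bj,
    _["matches"] = matches, _["mismatches"] = mismatches,
    _["gap_opens"] = gap_opens, _["gap_bases"] = gap_bases);
}

// Diagonals (j - i) of exact shared k-mers between a and b, one entry per
// hit. k <= 15 (2-bit packed); k-mers containing non-ACGT are skipped.
// [[Rcpp::export]]
IntegerVector seed_diagonals_cpp(std::string a, std::string b, int k) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> diags;
  if (n < k || m < k || k < 1 || k > 15) return IntegerVector(0);
  const uint32_t mask = (1u << (2 * k)) - 1;
  std::unordered_map<uint32_t, std::vector<int>> idx;
  idx.reserve((size_t)m * 2);
  uint32_t h = 0; int run = 0;
  for (int j = 0; j < m; ++j) {
    const int e = enc(b[j]);
    if (e > 3) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint32_t)e) & mask;
    if (++run >= k) idx[h].push_back(j - k + 2); // 1-based k-mer start
  }
  h = 0; run = 0;
  for (int i = 0; i < n; ++i) {
    const int e = enc(a[i]);
    if (e > 3) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint32_t)e) & mask;
    if (++run >= k) {
      auto it = idx.find(h);
      if (it != idx.end()) {
        const int astart = i - k + 2;
        for (int bstart : it->second) diags.push_back(bstart - astart);
      }
    }
  }
  return IntegerVector(diags.begin(), diags.end());
}
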