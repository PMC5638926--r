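#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Frameshift-aware local alignment of a protein query against one strand
// of a DNA window (dynamic programming over residue index i and the
// window position p of the last nucleotide of the codon aligned to i).
//
// Codon advances of 3 stay in frame; advances of 2 or 4 model a 1-nt
// deletion/insertion (frame switch) and pay fs_pen. Residue-vs-stop-codon
// matches pay stop_pen instead of a substitution score. Affine gaps
// (open+ext for the first element): Ix = unaligned residues, Iy =
// unaligned in-frame codons. Score rows are rolled (two rows live at a
// time); full byte traceback matrices reconstruct the best local path.
//
// ref:  0-based indices into the substitution matrix alphabet (length m).
// dna:  0=A,1=C,2=G,3=T, anything else = ambiguous (length L).
// codon_aa: length-64 map from codon index (16*n1+4*n2+n3) to alphabet
//   row, or -1 for stop codons.
//
// Returns best local path: score, per-residue alignment count, frame
// switch and internal stop positions (1-based residue coordinates), and
// the DNA span (1-based, on the given strand).
// [[Rcpp::export(name = ".fs_align")]]
List fs_align(const IntegerVector ref, const IntegerVector dna,
              const IntegerMatrix subst, const IntegerVector codon_aa,
              const int gap_open, const int gap_ext,
              const int stop_pen, const int fs_pen,
              const int ambig_score) {
  const int m = ref.size(), L = dna.size();
  const int NEG = -1000000000;
  if (L < 3 || m < 1)
    return List::create(_["score"] = NA_INTEGER);

  // codon index ending at p (1-based p >= 3), -2 if ambiguous
  std::vector<int> cidx(L + 1, -2);
  for (int p = 3; p <= L; ++p) {
    const int a = dna[p - 3], b = dna[p - 2], c = dna[p - 1];
    if (a >= 0 && a < 4 && b >= 0 && b < 4 && c >= 0 && c < 4)
      cidx[p] = 16 * a + 4 * b + c;
  }

  const size_t W = (size_t)L + 1;
  // rolling score rows (previous residue / current residue)
  std::vector<int> Mp(W, NEG), Mc(W, NEG), Ixp(W, NEG), Ixc(W, NEG),
      Iyp(W, NEG), Iyc(W, NEG);
  // traceback codes, full (byte) matrices
  // M: 0 start; else (k+1) + 4*scode, k: 0/1/2 = advance 3/2/4,
  //    scode: 0=M, 1=Ix, 2=Iy
  // Ix: 0 from M[i-1][p], 1 from Ix[i-1][p]
  // Iy: 0 from M[i][p-3], 1 from Iy[i][p-3]
  std::vector<signed char> tbM((size_t)(m + 1) * W, 0), tbIx((size_t)(m + 1) * W, 0),
      tbIy((size_t)(m + 1) * W, 0);

  int best = 0, bi = -1, bp = -1;
  const int adv[3] = {3, 2, 4};

  // substitution score per residue row, precomputed over window positions
  std::vector<int> srow(W, ambig_score);

  for (int i = 1; i <= m; ++i) {
    const size_t ti = (size_t)i * W;
    const int* Brow = &subst[(size_t)ref[i - 1]];  // column-major: subst(r, aa)
    const int na = subst.nrow();
    for (int p = 3; p <= L; ++p) {
      const int ci = cidx[p];
      if (ci < 0) srow[p] = ambig_score;
      else {
        const int aa = codon_aa[ci];
        srow[p] = (aa < 0) ? -stop_pen : Brow[(size_t)aa * na];
      }
    }
    std::fill(Mc.begin(), Mc.end(), NEG);
    std::fill(Ixc.begin(), Ixc.end(), NEG);
    std::fill(Iyc.begin(), Iyc.end(), NEG);
    for (int p = 3; p <= L; ++p) {
      // M: residue i aligned to codon ending at p
      int bestprev = 0; signed char code = 0;
      for (int k = 0; k < 3; ++k) {
        const int q = p - adv[k];
        if (q < 3) continue;
        const int pen = (k == 0) ? 0 : fs_pen;
        int v = Mp[q] - pen;
        if (v > bestprev) { bestprev = v; code = (signed char)(k + 1); }
        v = Ixp[q] - pen;
        if (v > bestprev) { bestprev = v; code = (signed char)(k + 1 + 4); }
        v = Iyp[q] - pen;
        if (v > bestprev) { bestprev = v; code = (signed char)(k + 1 + 8); }
      }
      const int mval = srow[p] + bestprev;
      Mc[p] = mval; tbM[ti + p] = code;
      // Ix: residue i unaligned at DNA position p
      {
        const int v1 = Mp[p] - gap_open - gap_ext;
        const int v2 = Ixp[p] - gap_ext;
        if (v1 >= v2) { Ixc[p] = v1; tbIx[ti + p] = 0; }
        else { Ixc[p] = v2; tbIx[ti + p] = 1; }
      }
      // Iy: codon ending at p unaligned
      if (p >= 6) {
        const int v1 = Mc[p - 3] - gap_open - gap_ext;
        const int v2 = Iyc[p - 3] - gap_ext;
        if (v1 >= v2) { Iyc[p] = v1; tbIy[ti + p] = 0; }
        else { Iyc[p] = v2; tbIy[ti + p] = 1; }
      }
      if (mval > best) { best = mval; bi = i; bp = p; }
    }
    std::swap(Mp, Mc); std::swap(Ixp, Ixc); std::swap(Iyp, Iyc);
  }

  if (bi < 0)
    return List::create(_["score"] = 0, _["n_aligned"] = 0,
                        _["ref_first"] = NA_INTEGER, _["ref_last"] = NA_INTEGER,
                        _["dna_first"] = NA_INTEGER, _["dna_last"] = NA_INTEGER,
                        _["stops"] = IntegerVector(0),
                        _["shifts"] = IntegerVector(0));

  // traceback from (bi, bp) in state M
  std::vector<int> stops, shifts, res_i, res_p;
  int i = bi, p = bp, st = 0;  // st: 0=M, 1=Ix, 2=Iy
  while (i > 0) {
    const size_t idx = (size_t)i * W + p;
    if (st == 0) {
      res_i.push_back(i); res_p.push_back(p);
      const int ci = cidx[p];
      if (ci >= 0 && codon_aa[ci] < 0) stops.push_back(i);
      const signed char code = tbM[idx];
      if (code == 0) break;                  // local start
      const int k = (code - 1) % 4;
      if (adv[k] != 3) shifts.push_back(i);
      st = (code - 1) / 4;
      p -= adv[k];
      i -= 1;
    } else if (st == 1) {
      st = (tbIx[idx] == 0) ? 0 : 1;
      i -= 1;
    } else {
      st = (tbIy[idx] == 0) ? 0 : 2;
      p -= 3;
    }
  }
  const int n_aligned = (int)res_i.size();
  return List::create(
      _["score"] = best,
      _["n_aligned"] = n_aligned,
      _["ref_first"] = res_i.back(), _["ref_last"] = res_i.front(),
      _["dna_first"] = res_p.back() - 2, _["dna_last"] = res_p.front(),
      _["stops"] = IntegerVector(stops.rbegin(), stops.rend()),
      _["shifts"] = IntegerVector(shifts.rbegin(), shifts.rend()));
}
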