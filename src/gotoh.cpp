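#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh).
//
// A gap of length L costs gap_open + L * gap_extend, i.e. the opening
// position is charged both penalties (NCBI "existence/extension" convention).
//
// Inputs are pre-encoded by the R wrapper:
//   qi, si : 0-based column indices into `sub` for each residue, or -1 for a
//            residue absent from the matrix (scores -1 against everything)
//   qc, sc : raw character codes, used for the identity count
//   qa, sa : TRUE where the residue is ambiguous (X, N, ...) and must never
//            count as an identity even when the characters match
//
// Determinism: the best cell is the maximal score with the smallest subject
// end position, then the smallest query end position; traceback prefers
// diagonal over gap-in-subject (query residue vs '-') over gap-in-query.
// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(IntegerVector qi, IntegerVector si,
                 IntegerVector qc, IntegerVector sc,
                 LogicalVector qa, LogicalVector sa,
                 IntegerMatrix sub, int gap_open, int gap_extend) {
  const int m = qi.size(), n = si.size();
  const int NEG = INT_MIN / 4;
  const int go = gap_open + gap_extend;  // cost of opening a length-1 gap
  const int ge = gap_extend;

  // traceback codes for H: 0 stop, 1 diag, 2 up (F, gap in subject), 3 left (E)
  std::vector<uint8_t> tbH((size_t)(m + 1) * (n + 1), 0);
  std::vector<uint8_t> tbE((size_t)(m + 1) * (n + 1), 0);  // 1 = opened from H
  std::vector<uint8_t> tbF((size_t)(m + 1) * (n + 1), 0);
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0);
  std::vector<int> Fprev(n + 1, NEG), Fcur(n + 1, NEG);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    int Ecur = NEG;
    Hcur[0] = 0;
    for (int j = 1; j <= n; ++j) {
      const size_t at = (size_t)i * (n + 1) + j;
      // E: gap in query (consume subject)
      int e_open = Hcur[j - 1] - go, e_ext = Ecur - ge;
      Ecur = (e_open >= e_ext) ? e_open : e_ext;
      tbE[at] = (e_open >= e_ext) ? 1 : 0;
      // F: gap in subject (consume query)
      int f_open = Hprev[j] - go, f_ext = Fprev[j] - ge;
      Fcur[j] = (f_open >= f_ext) ? f_open : f_ext;
      tbF[at] = (f_open >= f_ext) ? 1 : 0;
      // substitution score; residues outside the matrix score -1
      int sc_ij;
      if (qi[i - 1] < 0 || si[j - 1] < 0) sc_ij = -1;
      else sc_ij = sub(qi[i - 1], si[j - 1]);
      int diag = Hprev[j - 1] + sc_ij;
      // preference: diag > F (gap-in-subject) > E (gap-in-query) > stop
      int h = 0; uint8_t tb = 0;
      if (diag >= h && diag > 0) { h = diag; tb = 1; }
      if (Fcur[j] > h)           { h = Fcur[j]; tb = 2; }
      if (Ecur > h)              { h = Ecur; tb = 3; }
      Hcur[j] = h; tbH[at] = tb;
      if (h > best || (h == best && h > 0 && (j < bj || (j == bj && i < bi)))) {
        best = h; bi = i; bj = j;
      }
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }

  // traceback
  std::vector<int> qrow, srow;  // char codes, 45 ('-') for gaps
  int columns = 0, identities = 0, gaps = 0;
  int i = bi, j = bj;
  int qe = bi, se = bj;
  int state = 0;  // 0 = in H, 2 = in F run, 3 = in E run
  if (best > 0) {
    while (true) {
      const size_t at = (size_t)i * (n + 1) + j;
      int move;
      if (state == 0) {
        move = tbH[at];
        if (move == 0) break;
      } else {
        move = state;
      }
      if (move == 1) {
        ++columns;
        qrow.push_back(qc[i - 1]); srow.push_back(sc[j - 1]);
        if (qc[i - 1] == sc[j - 1] && !qa[i - 1] && !sa[j - 1]) ++identities;
        --i; --j; state = 0;
      } else if (move == 2) {  // gap in subject, consume query residue
        ++columns; ++gaps;
        qrow.push_back(qc[i - 1]); srow.push_back(45);
        state = tbF[at] ? 0 : 2;
        --i;
      } else {                 // gap in query, consume subject residue
        ++columns; ++gaps;
        qrow.push_back(45); srow.push_back(sc[j - 1]);
        state = tbE[at] ? 0 : 3;
        --j;
      }
    }
  }
  int qb = (best > 0) ? i : 0, sb = (best > 0) ? j : 0;
  if (best == 0) { qe = 0; se = 0; }
  std::reverse(qrow.begin(), qrow.end());
  std::reverse(srow.begin(), srow.end());

  return List::create(
    _["score"] = best,
    _["query_begin"] = qb, _["query_end"] = qe,
    _["subject_begin"] = sb, _["subject_end"] = se,
    _["columns"] = columns, _["identities"] = identities, _["gaps"] = gaps,
    _["aligned_query"] = IntegerVector(qrow.begin(), qrow.end()),
    _["aligned_subject"] = IntegerVector(srow.begin(), srow.end()));
}
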