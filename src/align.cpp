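#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Affine-gap alignment (Gotoh) over a precomputed position score matrix
// S[i][j] = score of aligning row unit i (profile column / residue of A)
// to column unit j (target residue / residue of B).
//
// Gap of length k costs gap_open + k * gap_extend (BLAST convention:
// the first gap residue pays open + extend).
//
// Deterministic tie-breaking: substitution > gap-in-target (consume row) >
// gap-in-column; in local mode the start cell is the leftmost-highest
// maximum (smallest row, then smallest column).
//
// mode: 0 = local (Smith-Waterman, empty alignment allowed),
//       1 = global (Needleman-Wunsch, end gaps penalized).
// [[Rcpp::export(name = ".dp_align")]]
List dp_align(NumericMatrix S, double gap_open, double gap_extend, int mode) {
  const int L = S.nrow(), M = S.ncol();
  const double GO = gap_open + gap_extend; // cost of first gap residue
  const double GE = gap_extend;
  const double NEG = -1e30;
  const bool local = (mode == 0);

  // state matrices, (L+1) x (M+1)
  std::vector<double> Mm((L + 1) * (M + 1), NEG);
  std::vector<double> Xm((L + 1) * (M + 1), NEG); // gap in target, consume row
  std::vector<double> Ym((L + 1) * (M + 1), NEG); // gap in row, consume column
  // traceback: for M, predecessor state at (i-1,j-1): 0 start, 1 M, 2 X, 3 Y
  // for X: 1 = opened from best(i-1,j), 2 = extended X(i-1,j); plus which
  // state the opening came from. Same for Y along j.
  std::vector<signed char> pM((L + 1) * (M + 1), 0);
  std::vector<signed char> pX((L + 1) * (M + 1), 0);
  std::vector<signed char> pY((L + 1) * (M + 1), 0);
  std::vector<signed char> argH((L + 1) * (M + 1), 0); // 1 M, 2 X, 3 Y

#define IDX(i, j) ((i) * (M + 1) + (j))

  Mm[IDX(0, 0)] = 0.0;
  argH[IDX(0, 0)] = 1;
  for (int i = 1; i <= L; ++i) {
    if (local) {
      Mm[IDX(i, 0)] = 0.0; argH[IDX(i, 0)] = 1;
    } else {
      Xm[IDX(i, 0)] = -GO - GE * (i - 1);
      pX[IDX(i, 0)] = (i == 1) ? 1 : 2;
      argH[IDX(i, 0)] = 2;
    }
  }
  for (int j = 1; j <= M; ++j) {
    if (local) {
      Mm[IDX(0, j)] = 0.0; argH[IDX(0, j)] = 1;
    } else {
      Ym[IDX(0, j)] = -GO - GE * (j - 1);
      pY[IDX(0, j)] = (j == 1) ? 1 : 3;
      argH[IDX(0, j)] = 3;
    }
  }

  double best = local ? 0.0 : NEG;
  int bi = 0, bj = 0;

  for (int i = 1; i <= L; ++i) {
    for (int j = 1; j <= M; ++j) {
      // M state: diagonal
      double dM = Mm[IDX(i - 1, j - 1)], dX = Xm[IDX(i - 1, j - 1)],
             dY = Ym[IDX(i - 1, j - 1)];
      double dbest = dM; signed char dptr = 1;
      if (dX > dbest) { dbest = dX; dptr = 2; }
      if (dY > dbest) { dbest = dY; dptr = 3; }
      if (local && dbest <= 0.0) { dbest = 0.0; dptr = 0; }
      double mv = (dbest <= NEG / 2) ? NEG : dbest + S(i - 1, j - 1);
      Mm[IDX(i, j)] = mv; pM[IDX(i, j)] = dptr;

      // X state: gap in target, consume row i
      double hUp = Mm[IDX(i - 1, j)]; signed char hUpArg = 1;
      if (Xm[IDX(i - 1, j)] > hUp) { hUp = Xm[IDX(i - 1, j)]; hUpArg = 2; }
      if (Ym[IDX(i - 1, j)] > hUp) { hUp = Ym[IDX(i - 1, j)]; hUpArg = 3; }
      double xOpen = (hUp <= NEG / 2) ? NEG : hUp - GO;
      double xExt = (Xm[IDX(i - 1, j)] <= NEG / 2) ? NEG : Xm[IDX(i - 1, j)] - GE;
      // prefer closing/opening from M on ties, then extension
      if (xOpen >= xExt) { Xm[IDX(i, j)] = xOpen; pX[IDX(i, j)] = hUpArg; }
      else { Xm[IDX(i, j)] = xExt; pX[IDX(i, j)] = 2; }

      // Y state: gap in row, consume column j
      double hLf = Mm[IDX(i, j - 1)]; signed char hLfArg = 1;
      if (Xm[IDX(i, j - 1)] > hLf) { hLf = Xm[IDX(i, j - 1)]; hLfArg = 2; }
      if (Ym[IDX(i, j - 1)] > hLf) { hLf = Ym[IDX(i, j - 1)]; hLfArg = 3; }
      double yOpen = (hLf <= NEG / 2) ? NEG : hLf - GO;
      double yExt = (Ym[IDX(i, j - 1)] <= NEG / 2) ? NEG : Ym[IDX(i, j - 1)] - GE;
      if (yOpen >= yExt) { Ym[IDX(i, j)] = yOpen; pY[IDX(i, j)] = hLfArg; }
      else { Ym[IDX(i, j)] = yExt; pY[IDX(i, j)] = 3; }

      // cell best with precedence M > X > Y
      double h = Mm[IDX(i, j)]; signed char a = 1;
      if (Xm[IDX(i, j)] > h) { h = Xm[IDX(i, j)]; a = 2; }
      if (Ym[IDX(i, j)] > h) { h = Ym[IDX(i, j)]; a = 3; }
      argH[IDX(i, j)] = a;

      if (local) {
        // local alignments end in a substitution (M state)
        if (Mm[IDX(i, j)] > best) { best = Mm[IDX(i, j)]; bi = i; bj = j; }
      }
    }
  }

  if (!local) {
    best = Mm[IDX(L, M)];
    signed char a = 1;
    if (Xm[IDX(L, M)] > best) { best = Xm[IDX(L, M)]; a = 2; }
    if (Ym[IDX(L, M)] > best) { best = Ym[IDX(L, M)]; a = 3; }
    argH[IDX(L, M)] = a;
    bi = L; bj = M;
  }

  // traceback: pM/pX/pY store the predecessor *state* directly
  std::vector<int> ai, bjv; // row index or 0, column index or 0
  int i = bi, j = bj;
  signed char state = local ? 1 : argH[IDX(L, M)];
  if (local && best <= 0.0) { i = 0; j = 0; state = 0; best = 0.0; }
  while (state != 0 && (i > 0 || j > 0)) {
    if (state == 1) { // M: substitution at (i, j)
      ai.push_back(i); bjv.push_back(j);
      signed char prev = pM[IDX(i, j)];
      --i; --j;
      if (prev == 0) break; // local alignment start
      state = prev;
    } else if (state == 2) { // X: row i against a gap
      ai.push_back(i); bjv.push_back(0);
      state = pX[IDX(i, j)];
      --i;
    } else { // Y: gap against column j
      ai.push_back(0); bjv.push_back(j);
      state = pY[IDX(i, j)];
      --j;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bjv.begin(), bjv.end());

  return List::create(_["score"] = best,
                      _["row_index"] = IntegerVector(ai.begin(), ai.end()),
                      _["col_index"] = IntegerVector(bjv.begin(), bjv.end()));
}
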