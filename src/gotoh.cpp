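#include <Rcpp.h>
using namespace Rcpp;

// Global affine-gap alignment (Gotoh) over a precomputed cell-score matrix.
// sm(i, j) holds the score of aligning unit i of A (residue or profile
// column) with unit j of B. Opening a gap costs gap_open + gap_extend at the
// first gapped position, each further position gap_extend; end gaps are
// penalised like any other gap.
//
// Three-state automaton: M aligns A_i with B_j; X puts a gap in A (consumes
// B_j); Y puts a gap in B (consumes A_i). Entering X or Y from any other
// state pays the opening cost, staying pays the extension. On equal scores
// the predecessor preference is M over X over Y, and the final state is
// chosen with the same preference, so the traced alignment is deterministic.
//
// Returns 1-based index vectors a_path / b_path over the merged columns
// (0 marks a gap) and the optimal score.

static const double NEG_INF = -1e300;

// [[Rcpp::export]]
List gotoh_align_cpp(NumericMatrix sm, double gap_open, double gap_extend) {
  const int n = sm.nrow(), m = sm.ncol();
  const double go = gap_open + gap_extend, ge = gap_extend;
  const int R = n + 1, C = m + 1;

  std::vector<double> M(R * C, NEG_INF), X(R * C, NEG_INF), Y(R * C, NEG_INF);
  // ptr stores the predecessor state (0=M, 1=X, 2=Y) for each cell/state
  std::vector<signed char> pM(R * C, -1), pX(R * C, -1), pY(R * C, -1);
  auto at = [C](int i, int j) { return i * C + j; };

  M[at(0, 0)] = 0.0;
  for (int j = 1; j <= m; ++j) {
    X[at(0, j)] = -go - ge * (j - 1);
    pX[at(0, j)] = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= n; ++i) {
    Y[at(i, 0)] = -go - ge * (i - 1);
    pY[at(i, 0)] = (i == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int d = at(i - 1, j - 1), u = at(i - 1, j), l = at(i, j - 1),
                c = at(i, j);
      // M: diagonal from any state, preference M > X > Y on ties
      double best = M[d]; signed char arg = 0;
      if (X[d] > best) { best = X[d]; arg = 1; }
      if (Y[d] > best) { best = Y[d]; arg = 2; }
      M[c] = best + sm(i - 1, j - 1);
      pM[c] = arg;
      // X: gap in A, consume B_j (move left)
      best = M[l] - go; arg = 0;
      if (X[l] - ge > best) { best = X[l] - ge; arg = 1; }
      if (Y[l] - go > best) { best = Y[l] - go; arg = 2; }
      X[c] = best; pX[c] = arg;
      // Y: gap in B, consume A_i (move up)
      best = M[u] - go; arg = 0;
      if (X[u] - go > best) { best = X[u] - go; arg = 1; }
      if (Y[u] - ge > best) { best = Y[u] - ge; arg = 2; }
      Y[c] = best; pY[c] = arg;
    }
  }

  const int e = at(n, m);
  double score = M[e]; int state = 0;
  if (X[e] > score) { score = X[e]; state = 1; }
  if (Y[e] > score) { score = Y[e]; state = 2; }

  std::vector<int> ap, bp;
  ap.reserve(n + m); bp.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int c = at(i, j);
    if (state == 0) {
      ap.push_back(i); bp.push_back(j);
      state = pM[c]; --i; --j;
    } else if (state == 1) {
      ap.push_back(0); bp.push_back(j);
      state = pX[c]; --j;
    } else {
      ap.push_back(i); bp.push_back(0);
      state = pY[c]; --i;
    }
  }
  std::reverse(ap.begin(), ap.end());
  std::reverse(bp.begin(), bp.end());
  return List::create(_["a_path"] = wrap(ap), _["b_path"] = wrap(bp),
                      _["score"] = score);
}
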