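#include <Rcpp.h>
using namespace Rcpp;

// Global profile-profile alignment with affine gaps (end gaps charged).
// A and B are integer matrices (rows = sequences, cols = alignment columns),
// entries 0 for gap or 1..K indexing into the substitution matrix `submat`.
// Column-column score is the average substitution score over all residue
// pairs; pairs involving a gap contribute 0.
// Returns two integer vectors over merged columns: the source column in A
// (0 if a gap column is inserted into A) and likewise for B.
// Traceback tie preference: diagonal, then gap inserted into A (column of B
// against gap), then gap inserted into B.
// [[Rcpp::export(name = ".profile_align_cpp")]]
List profile_align_cpp(IntegerMatrix A, IntegerMatrix B, NumericMatrix submat,
                       double gap_open, double gap_ext) {
  const int m = A.ncol(), n = B.ncol();
  const int ra = A.nrow(), rb = B.nrow();
  const int K = submat.nrow();
  const double NEG = -1e30;

  // residue counts per column
  NumericMatrix ca(m, K), cb(n, K);
  for (int i = 0; i < m; ++i)
    for (int r = 0; r < ra; ++r) {
      int v = A(r, i);
      if (v > 0) ca(i, v - 1) += 1.0;
    }
  for (int j = 0; j < n; ++j)
    for (int r = 0; r < rb; ++r) {
      int v = B(r, j);
      if (v > 0) cb(j, v - 1) += 1.0;
    }
  // sa = ca %*% submat, then score(i,j) = sa[i,] . cb[j,] / (ra*rb)
  NumericMatrix sa(m, K);
  for (int i = 0; i < m; ++i)
    for (int x = 0; x < K; ++x) {
      double cx = ca(i, x);
      if (cx == 0.0) continue;
      for (int y = 0; y < K; ++y) sa(i, y) += cx * submat(x, y);
    }
  const double denom = (double) ra * (double) rb;

  // DP matrices: Mm diagonal, Gx = gap inserted into B (A column vs gap),
  // Gy = gap inserted into A (B column vs gap).
  NumericMatrix Mm(m + 1, n + 1), Gx(m + 1, n + 1), Gy(m + 1, n + 1);
  const double open_cost = gap_open + gap_ext;
  Mm(0, 0) = 0.0; Gx(0, 0) = NEG; Gy(0, 0) = NEG;
  for (int i = 1; i <= m; ++i) {
    Mm(i, 0) = NEG;
    Gx(i, 0) = -(gap_open + gap_ext * i);
    Gy(i, 0) = NEG;
  }
  for (int j = 1; j <= n; ++j) {
    Mm(0, j) = NEG;
    Gx(0, j) = NEG;
    Gy(0, j) = -(gap_open + gap_ext * j);
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double s = 0.0;
      for (int y = 0; y < K; ++y) s += sa(i - 1, y) * cb(j - 1, y);
      s /= denom;
      double prev = std::max(Mm(i - 1, j - 1),
                             std::max(Gx(i - 1, j - 1), Gy(i - 1, j - 1)));
      Mm(i, j) = prev + s;
      Gx(i, j) = std::max(std::max(Mm(i - 1, j) - open_cost,
                                   Gx(i - 1, j) - gap_ext),
                          Gy(i - 1, j) - open_cost);
      Gy(i, j) = std::max(std::max(Mm(i, j - 1) - open_cost,
                                   Gy(i, j - 1) - gap_ext),
                          Gx(i, j - 1) - open_cost);
    }
  }

  // traceback
  std::vector<int> ai, bi;
  int i = m, j = n;
  int state; // 0 = M, 1 = Gy (gap into A), 2 = Gx (gap into B)
  double best = Mm(m, n); state = 0;
  if (Gy(m, n) > best) { best = Gy(m, n); state = 1; }
  if (Gx(m, n) > best) { best = Gx(m, n); state = 2; }
  while (i > 0 || j > 0) {
    if (state == 0) {
      ai.push_back(i); bi.push_back(j);
      double prev = Mm(i - 1, j - 1) ;
      double target = Mm(i, j);
      // which predecessor achieved it (tie: M, Gy, Gx)
      double s = target - std::max(Mm(i - 1, j - 1),
                   std::max(Gx(i - 1, j - 1), Gy(i - 1, j - 1)));
      double need = target - s;
      if (Mm(i - 1, j - 1) >= need - 1e-9) state = 0;
      else if (Gy(i - 1, j - 1) >= need - 1e-9) state = 1;
      else state = 2;
      --i; --j;
      (void) prev;
    } else if (state == 1) { // column of B against gap in A
      ai.push_back(0); bi.push_back(j);
      double target = Gy(i, j);
      if (std::abs(target - (Mm(i, j - 1) - open_cost)) < 1e-9) state = 0;
      else if (std::abs(target - (Gy(i, j - 1) - gap_ext)) < 1e-9) state = 1;
      else state = 2;
      --j;
    } else { // column of A against gap in B
      ai.push_back(i); bi.push_back(0);
      double target = Gx(i, j);
      if (std::abs(target - (Mm(i - 1, j) - open_cost)) < 1e-9) state = 0;
      else if (std::abs(target - (Gx(i - 1, j) - gap_ext)) < 1e-9) state = 2;
      else state = 1;
      --i;
    }
    if (i == 0 && j == 0) break;
    if (i == 0 && j > 0 && state == 0) state = 1;
    if (j == 0 && i > 0 && state == 0) state = 2;
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["a"] = wrap(ai), _["b"] = wrap(bi),
                      _["score"] = best);
}
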