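#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps, Gotoh three-state
// recursion, on a precomputed column-vs-column score matrix. Operating on
// scores rather than residues lets the same kernel drive both pairwise
// sequence alignment and profile-profile alignment during progressive MSA.
//
// Gap of length L costs gap_open + L * gap_ext (both terminal and internal
// gaps are penalized). Tie-breaking during traceback is fixed: prefer the
// aligned (diagonal) state, then a gap in the first input, then a gap in
// the second.
//
// Returns 1-based column indices into A and B for each alignment column,
// 0 marking a gap, plus the optimal score.
// [[Rcpp::export]]
List gotoh_align(NumericMatrix cell, double gap_open, double gap_ext) {
  const int n = cell.nrow();   // columns of A
  const int m = cell.ncol();   // columns of B
  const double NEG = -1e30;
  const double open = gap_open + gap_ext;

  // state 0 = M (aligned), 1 = Ia (gap in A, consumes B), 2 = Ib (gap in B)
  std::vector<double> M((n + 1) * (m + 1), NEG);
  std::vector<double> Ia((n + 1) * (m + 1), NEG);
  std::vector<double> Ib((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int j = 1; j <= m; ++j) Ia[at(0, j)] = -(gap_open + j * gap_ext);
  for (int i = 1; i <= n; ++i) Ib[at(i, 0)] = -(gap_open + i * gap_ext);

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = cell(i - 1, j - 1);
      double dM = M[at(i - 1, j - 1)], dIa = Ia[at(i - 1, j - 1)],
             dIb = Ib[at(i - 1, j - 1)];
      double best = dM;
      if (dIa > best) best = dIa;
      if (dIb > best) best = dIb;
      M[at(i, j)] = s + best;

      double aM = M[at(i, j - 1)] - open, aIa = Ia[at(i, j - 1)] - gap_ext,
             aIb = Ib[at(i, j - 1)] - open;
      best = aM;
      if (aIa > best) best = aIa;
      if (aIb > best) best = aIb;
      Ia[at(i, j)] = best;

      double bM = M[at(i - 1, j)] - open, bIa = Ia[at(i - 1, j)] - open,
             bIb = Ib[at(i - 1, j)] - gap_ext;
      best = bM;
      if (bIa > best) best = bIa;
      if (bIb > best) best = bIb;
      Ib[at(i, j)] = best;
    }
  }
  // choose final state with the fixed preference M > Ia > Ib
  double fM = M[at(n, m)], fIa = Ia[at(n, m)], fIb = Ib[at(n, m)];
  int state;
  double score;
  if (fM >= fIa && fM >= fIb) { state = 0; score = fM; }
  else if (fIa >= fIb) { state = 1; score = fIa; }
  else { state = 2; score = fIb; }

  std::vector<int> pa, pb;
  pa.reserve(n + m);
  pb.reserve(n + m);
  int i = n, j = m;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0 || j == 0) stop("traceback failure in aligned state");
      pa.push_back(i);
      pb.push_back(j);
      double target = M[at(i, j)] - cell(i - 1, j - 1);
      --i; --j;
      if (std::abs(M[at(i, j)] - target) < eps) state = 0;
      else if (std::abs(Ia[at(i, j)] - target) < eps) state = 1;
      else state = 2;
    } else if (state == 1) {
      if (j == 0) stop("traceback failure in gap-in-A state");
      pa.push_back(0);
      pb.push_back(j);
      double cur = Ia[at(i, j)];
      --j;
      if (std::abs(M[at(i, j)] - (cur + open)) < eps) state = 0;
      else if (std::abs(Ia[at(i, j)] - (cur + gap_ext)) < eps) state = 1;
      else state = 2;
    } else {
      if (i == 0) stop("traceback failure in gap-in-B state");
      pa.push_back(i);
      pb.push_back(0);
      double cur = Ib[at(i, j)];
      --i;
      if (std::abs(M[at(i, j)] - (cur + open)) < eps) state = 0;
      else if (std::abs(Ia[at(i, j)] - (cur + open)) < eps) state = 1;
      else state = 2;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["a"] = wrap(pa), _["b"] = wrap(pb),
                      _["score"] = score);
}

// Pairwise column statistics for a coded multiple alignment
// (rows = sequences; 0 = gap, positive integers = residue codes, with the
// code for the ambiguity character passed in x_code so it can be excluded
// from identity counts). Returns, for every ordered pair (upper triangle
// mirrored):
//   ncomp - columns ungapped in both rows (pairwise deletion)
//   ndiff - of those, columns where the residues differ (X vs X counts as
//           a difference: the ambiguity code never matches)
//   ncov  - columns where at least one row has a residue (identity
//           denominator for MSA-derived percent identity)
//   nid   - columns counted as identical (equal, ungapped, not X)
// [[Rcpp::export]]
List msa_pair_stats(IntegerMatrix msa, int x_code) {
  const int n = msa.nrow();
  const int w = msa.ncol();
  IntegerMatrix ncomp(n, n), ndiff(n, n), ncov(n, n), nid(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int comp = 0, diff = 0, cov = 0, id = 0;
      for (int k = 0; k < w; ++k) {
        int a = msa(i, k), b = msa(j, k);
        if (a == 0 && b == 0) continue;
        ++cov;
        if (a == 0 || b == 0) continue;
        ++comp;
        if (a == b && a != x_code) ++id;
        if (a != b || a == x_code) ++diff;
      }
      ncomp(i, j) = ncomp(j, i) = comp;
      ndiff(i, j) = ndiff(j, i) = diff;
      ncov(i, j) = ncov(j, i) = cov;
      nid(i, j) = nid(j, i) = id;
    }
  }
  return List::create(_["ncomp"] = ncomp, _["ndiff"] = ndiff,
                      _["ncov"] = ncov, _["nid"] = nid);
}
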