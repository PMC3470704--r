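#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Open-ended dynamic time warping between two curves sampled on a shared grid.
//
// Steps {(1,0),(0,1),(1,1)}, squared-difference local cost. The path may start
// at (i,0) or (0,j) with i,j <= slack and end at (n-1,j) or (i,m-1) within the
// same slack of the far corner. Deterministic tie-breaks: prefer the diagonal
// step, then advancing the first (query) index, then the second; a fresh start
// is taken only when strictly cheaper than continuing; among equal-cost end
// cells the one nearest the (n-1,m-1) corner wins (larger i on ties).
//
// Traceback pointer codes: 0 = path start, 1 = diagonal, 2 = from (i-1,j),
// 3 = from (i,j-1).
static double dtw_core(const double* a, int n, const double* b, int m, int slack,
                       std::vector<int>& pi, std::vector<int>& pj) {
  std::vector<double> D((size_t)n * m);
  std::vector<signed char> P((size_t)n * m);
  const auto idx = [m](int i, int j) { return (size_t)i * m + j; };

  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      const double diff = a[i] - b[j];
      const double c = diff * diff;
      double best;
      signed char p;
      if (i == 0 && j == 0) {
        best = 0.0; p = 0;
      } else if (i == 0) {
        best = D[idx(0, j - 1)]; p = 3;
        if (j <= slack && 0.0 < best) { best = 0.0; p = 0; }
      } else if (j == 0) {
        best = D[idx(i - 1, 0)]; p = 2;
        if (i <= slack && 0.0 < best) { best = 0.0; p = 0; }
      } else {
        best = D[idx(i - 1, j - 1)]; p = 1;
        if (D[idx(i - 1, j)] < best) { best = D[idx(i - 1, j)]; p = 2; }
        if (D[idx(i, j - 1)] < best) { best = D[idx(i, j - 1)]; p = 3; }
      }
      D[idx(i, j)] = best + c;
      P[idx(i, j)] = p;
    }
  }

  int ei = n - 1, ej = m - 1;
  double bestc = D[idx(ei, ej)];
  for (int s = 1; s <= slack; ++s) {
    if (m - 1 - s >= 0 && D[idx(n - 1, m - 1 - s)] < bestc) {
      bestc = D[idx(n - 1, m - 1 - s)]; ei = n - 1; ej = m - 1 - s;
    }
    if (n - 1 - s >= 0 && D[idx(n - 1 - s, m - 1)] < bestc) {
      bestc = D[idx(n - 1 - s, m - 1)]; ei = n - 1 - s; ej = m - 1;
    }
  }

  pi.clear(); pj.clear();
  int i = ei, j = ej;
  for (;;) {
    pi.push_back(i); pj.push_back(j);
    const signed char p = P[idx(i, j)];
    if (p == 0) break;
    if (p == 1) { --i; --j; }
    else if (p == 2) { --i; }
    else { --j; }
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
  return bestc;
}

// Mean time-shift along a path: for each distinct query index i the mean of
// ages[j] - ages[i] over its matched reference points, then the mean of those
// per-point shifts. Path entries with equal i are consecutive by monotonicity.
static double mean_shift_core(const std::vector<int>& pi, const std::vector<int>& pj,
                              const double* agesq, const double* agesr) {
  double tot = 0.0;
  int nu = 0;
  size_t k = 0;
  while (k < pi.size()) {
    size_t k2 = k;
    double s = 0.0;
    int c = 0;
    while (k2 < pi.size() && pi[k2] == pi[k]) {
      s += agesr[pj[k2]] - agesq[pi[k]];
      ++c; ++k2;
    }
    tot += s / c;
    ++nu;
    k = k2;
  }
  return tot / nu;
}

// [[Rcpp::export]]
List dtw_align_cpp(NumericVector a, NumericVector b, int slack) {
  std::vector<int> pi, pj;
  double cost = dtw_core(a.begin(), a.size(), b.begin(), b.size(), slack, pi, pj);
  IntegerVector ri(pi.size()), rj(pj.size());
  for (size_t k = 0; k < pi.size(); ++k) { ri[k] = pi[k] + 1; rj[k] = pj[k] + 1; }
  return List::create(_["i"] = ri, _["j"] = rj, _["cost"] = cost);
}

// Batched bidirectional alignment over replicate curve pairs (columns of A/B
// on a shared age grid). Column r of the result: mean shift aligning A->B
// (A as query) and B->A.
// [[Rcpp::export]]
NumericMatrix dtw_shift_batch(NumericMatrix A, NumericMatrix B,
                              NumericVector ages, int slack) {
  const int R = A.ncol();
  if (B.ncol() != R) stop("A and B must have the same number of replicate columns");
  if (A.nrow() != ages.size() || B.nrow() != ages.size())
    stop("curve length must match the age grid");
  NumericMatrix out(R, 2);
  std::vector<int> pi, pj;
  const double* ag = ages.begin();
  for (int r = 0; r < R; ++r) {
    dtw_core(&A(0, r), A.nrow(), &B(0, r), B.nrow(), slack, pi, pj);
    out(r, 0) = mean_shift_core(pi, pj, ag, ag);
    dtw_core(&B(0, r), B.nrow(), &A(0, r), A.nrow(), slack, pi, pj);
    out(r, 1) = mean_shift_core(pi, pj, ag, ag);
  }
  return out;
}
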