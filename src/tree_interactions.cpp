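// Exact interventional Shapley values and pairwise Shapley interaction
// values for tree ensembles.
//
// For one explained row x, one background row b and one tree, the coalition
// value v(S) = f(mix(x_S, b_!S)) decomposes over leaves: a leaf is reached
// by the mixed row iff every feature the path constrains to x's side is in
// S (set A) and every feature constrained to b's side is outside S (set B).
// Each leaf therefore contributes val * 1{A <= S, B disjoint S}, a game
// whose Shapley values and interaction indices have closed forms depending
// only on (|A|, |B|, p). Those per-(a,b) constants are precomputed in R and
// passed in as lookup tables. Subtrees reachable by neither x nor b are
// pruned, so the cost per (x, b, tree) is governed by the number of split
// nodes where x and b diverge, not by 2^p.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

struct Frame {
  int node;
  uint64_t A;
  uint64_t B;
};

// [[Rcpp::export]]
List tree_interactions_cpp(IntegerVector tree_offset, IntegerVector feature,
                           NumericVector threshold, IntegerVector left,
                           IntegerVector right, NumericVector value,
                           NumericMatrix X, NumericMatrix B,
                           NumericMatrix SA, NumericMatrix SBt,
                           NumericMatrix IAA, NumericMatrix IAB,
                           NumericMatrix IBB) {
  const int n = X.nrow(), p = X.ncol(), m = B.nrow();
  const int T = tree_offset.size() - 1;
  NumericMatrix phi(n, p);
  NumericVector Phi(Dimension(n, p, p));
  double *phiv = REAL(phi.get__());
  double *Phiv = REAL(Phi.get__());
  const double invTm = 1.0 / (double(T) * double(m));
  std::vector<Frame> stack;
  stack.reserve(256);
  int idxA[64], idxB[64];

  for (int i = 0; i < n; ++i) {
    for (int bi = 0; bi < m; ++bi) {
      for (int t = 0; t < T; ++t) {
        stack.push_back({tree_offset[t], 0ULL, 0ULL});
        while (!stack.empty()) {
          Frame fr = stack.back();
          stack.pop_back();
          int f = feature[fr.node];
          if (f < 0) {  // leaf
            int a = __builtin_popcountll(fr.A);
            int b = __builtin_popcountll(fr.B);
            if (a + b == 0) continue;  // same leaf for x and b: constant
            double val = value[fr.node] * invTm;
            int na = 0, nb = 0;
            for (uint64_t mm = fr.A; mm; mm &= mm - 1)
              idxA[na++] = __builtin_ctzll(mm);
            for (uint64_t mm = fr.B; mm; mm &= mm - 1)
              idxB[nb++] = __builtin_ctzll(mm);
            const double sa = val * SA(a, b), sb = val * SBt(a, b);
            for (int j = 0; j < na; ++j) phiv[i + n * idxA[j]] += sa;
            for (int j = 0; j < nb; ++j) phiv[i + n * idxB[j]] += sb;
            if (p >= 2) {
              const double iaa = val * IAA(a, b);
              const double iab = val * IAB(a, b);
              const double ibb = val * IBB(a, b);
              for (int j = 0; j < na; ++j)
                for (int k = j + 1; k < na; ++k) {
                  Phiv[i + n * (idxA[j] + p * idxA[k])] += iaa;
                  Phiv[i + n * (idxA[k] + p * idxA[j])] += iaa;
                }
              for (int j = 0; j < na; ++j)
                for (int k = 0; k < nb; ++k) {
                  Phiv[i + n * (idxA[j] + p * idxB[k])] += iab;
                  Phiv[i + n * (idxB[k] + p * idxA[j])] += iab;
                }
              for (int j = 0; j < nb; ++j)
                for (int k = j + 1; k < nb; ++k) {
                  Phiv[i + n * (idxB[j] + p * idxB[k])] += ibb;
                  Phiv[i + n * (idxB[k] + p * idxB[j])] += ibb;
                }
            }
            continue;
          }
          const double thr = threshold[fr.node];
          const bool xl = X(i, f) <= thr;
          const bool bl = B(bi, f) <= thr;
          const uint64_t bit = 1ULL << f;
          if (xl == bl) {
            stack.push_back({xl ? left[fr.node] : right[fr.node],
                             fr.A, fr.B});
          } else {
            if (!(fr.B & bit))  // x-side child: feature must be in S
              stack.push_back({xl ? left[fr.node] : right[fr.node],
                               fr.A | bit, fr.B});
            if (!(fr.A & bit))  // b-side child: feature must be out of S
              stack.push_back({bl ? left[fr.node] : right[fr.node],
                               fr.A, fr.B | bit});
          }
        }
      }
    }
  }
  // Diagonal holds the main-effect remainder so each row sums to phi_j.
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) {
      double off = 0.0;
      for (int k = 0; k < p; ++k)
        if (k != j) off += Phiv[i + n * (j + p * k)];
      Phiv[i + n * (j + p * j)] = phiv[i + n * j] - off;
    }
  return List::create(_["phi"] = phi, _["Phi"] = Phi);
}

// Evaluate the ensemble (mean of per-tree leaf values) from the flattened
// structure; used to validate the structure extraction against the
// learner's own predictions.
// [[Rcpp::export]]
NumericVector forest_predict_cpp(IntegerVector tree_offset,
                                 IntegerVector feature,
                                 NumericVector threshold,
                                 IntegerVector left, IntegerVector right,
                                 NumericVector value, NumericMatrix X) {
  const int n = X.nrow();
  const int T = tree_offset.size() - 1;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int t = 0; t < T; ++t) {
      int node = tree_offset[t];
      while (feature[node] >= 0) {
        node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                        : right[node];
      }
      acc += value[node];
    }
    out[i] = acc / T;
  }
  return out;
}
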