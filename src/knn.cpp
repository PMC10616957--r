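#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact K-nearest-neighbour search by brute force over all pairs.
// X is events x d (row-major access via column pointers); returns the K
// nearest neighbour indices (1-based, self excluded) and Euclidean
// distances per event.  O(n^2 d) time, O(nK) memory; intended for scopes
// up to a few times 1e4 events.
// [[Rcpp::export(name = ".knn_brute")]]
List knn_brute(NumericMatrix X, int K) {
  const int n = X.nrow(), d = X.ncol();
  if (K >= n) stop("K must be smaller than the number of events");
  IntegerMatrix idx(n, K);
  NumericMatrix dst(n, K);
  std::vector<double> bestd(K);
  std::vector<int> besti(K);
  const double *xp = REAL(X);
  for (int i = 0; i < n; ++i) {
    int m = 0;              // current heap fill
    double worst = R_PosInf;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = xp[i + (size_t)c * n] - xp[j + (size_t)c * n];
        s += diff * diff;
        if (s > worst) break;
      }
      if (m < K) {
        bestd[m] = s; besti[m] = j; ++m;
        if (m == K) {
          worst = 0.0;
          for (int k = 0; k < K; ++k) if (bestd[k] > worst) worst = bestd[k];
        }
      } else if (s < worst) {
        // replace current worst
        int wi = 0; double wv = -1.0;
        for (int k = 0; k < K; ++k) if (bestd[k] > wv) { wv = bestd[k]; wi = k; }
        bestd[wi] = s; besti[wi] = j;
        wv = 0.0;
        for (int k = 0; k < K; ++k) if (bestd[k] > wv) wv = bestd[k];
        worst = wv;
      }
    }
    // sort the K found by distance (insertion sort, K is small)
    for (int a = 1; a < K; ++a) {
      double dv = bestd[a]; int iv = besti[a];
      int b = a - 1;
      while (b >= 0 && (bestd[b] > dv ||
             (bestd[b] == dv && besti[b] > iv))) {
        bestd[b + 1] = bestd[b]; besti[b + 1] = besti[b]; --b;
      }
      bestd[b + 1] = dv; besti[b + 1] = iv;
    }
    for (int k = 0; k < K; ++k) {
      idx(i, k) = besti[k] + 1;
      dst(i, k) = std::sqrt(bestd[k]);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dst);
}

// Assign each row of X to the nearest row of C (squared Euclidean).
// Returns 1-based centroid indices.
// [[Rcpp::export(name = ".nn_assign")]]
IntegerVector nn_assign(NumericMatrix X, NumericMatrix C) {
  const int n = X.nrow(), d = X.ncol(), m = C.nrow();
  if (C.ncol() != d) stop("dimension mismatch");
  IntegerVector out(n);
  const double *xp = REAL(X), *cp = REAL(C);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf; int bi = 0;
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = xp[i + (size_t)c * n] - cp[j + (size_t)c * m];
        s += diff * diff;
        if (s > best) break;
      }
      if (s < best) { best = s; bi = j; }
    }
    out[i] = bi + 1;
  }
  return out;
}
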