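#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Exponentially weighted nearest-neighbour prediction on a delay embedding.
//
// emb    : embedding matrix, one row per reconstructed state vector
// times  : time index of each row (used for leave-one-out exclusion: a
//          library row is never a neighbour of a prediction row that shares
//          its time index)
// target : value to be predicted, aligned with rows of emb (NA allowed; rows
//          with NA target are never used as library neighbours)
// lib    : 0-based row indices forming the library
// pred   : 0-based row indices at which predictions are made
// k      : number of neighbours (simplex convention: E + 1)
// excl   : temporal exclusion radius (Theiler window); library rows with
//          |times[lib] - times[pred]| <= excl are never neighbours
//          (0 = exclude only the prediction row itself)
//
// Weights are w_i = exp(-d_i / d_1) with d_1 the nearest distance; if
// d_1 == 0, exact-match neighbours get weight 1 and all others weight 0
// (the limit of the kernel). Ties in distance are broken by library order,
// which is deterministic for a fixed library vector.
// [[Rcpp::export]]
NumericVector nn_forecast(const NumericMatrix& emb,
                          const IntegerVector& times,
                          const NumericVector& target,
                          const IntegerVector& lib,
                          const IntegerVector& pred,
                          const int k,
                          const int excl) {
  const int E = emb.ncol();
  const int nrow = emb.nrow();
  const int n_lib = lib.size();
  const int n_pred = pred.size();
  if (k < 1) stop("k must be >= 1");
  const double* pe = &emb(0, 0);   // column-major
  const double inf = std::numeric_limits<double>::infinity();

  for (int j = 0; j < n_lib; ++j)
    if (lib[j] < 0 || lib[j] >= nrow) stop("library index out of range");

  NumericVector out(n_pred, NA_REAL);
  std::vector<double> d2(n_lib);
  std::vector<int> ord(n_lib);

  for (int p = 0; p < n_pred; ++p) {
    const int pr = pred[p];
    if (pr < 0 || pr >= nrow) stop("prediction index out of range");
    int eligible = 0;
    for (int j = 0; j < n_lib; ++j) {
      const int lr = lib[j];
      if (std::abs(times[lr] - times[pr]) <= excl ||
          NumericVector::is_na(target[lr])) {
        d2[j] = inf;
        continue;
      }
      double acc = 0.0;
      for (int c = 0; c < E; ++c) {
        const double diff = pe[c * nrow + pr] - pe[c * nrow + lr];
        acc += diff * diff;
      }
      d2[j] = acc;
      ++eligible;
    }
    if (eligible < k)
      stop("fewer than k eligible neighbours (library too small)");
    for (int j = 0; j < n_lib; ++j) ord[j] = j;
    // k nearest, ties broken by library order
    std::nth_element(ord.begin(), ord.begin() + (k - 1), ord.end(),
                     [&](int a, int b) {
                       return d2[a] < d2[b] || (d2[a] == d2[b] && a < b);
                     });
    std::sort(ord.begin(), ord.begin() + k,
              [&](int a, int b) {
                return d2[a] < d2[b] || (d2[a] == d2[b] && a < b);
              });

    const double d1 = std::sqrt(d2[ord[0]]);
    double wsum = 0.0, ysum = 0.0;
    if (d1 <= 0.0) {
      // exact matches carry all the weight
      for (int j = 0; j < k; ++j) {
        if (d2[ord[j]] <= 0.0) {
          ysum += target[lib[ord[j]]];
          wsum += 1.0;
        }
      }
    } else {
      for (int j = 0; j < k; ++j) {
        const double w = std::exp(-std::sqrt(d2[ord[j]]) / d1);
        ysum += w * target[lib[ord[j]]];
        wsum += w;
      }
    }
    out[p] = ysum / wsum;
  }
  return out;
}
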