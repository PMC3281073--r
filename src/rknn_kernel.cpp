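#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Squared Euclidean distance between row a of A and row b of B over the
// 0-based column indices in `cols`. Matrices are column-major; small m, so
// the strided access is acceptable.
static inline double dist2(const NumericMatrix &A, int a,
                           const NumericMatrix &B, int b,
                           const std::vector<int> &cols) {
  double s = 0.0;
  for (size_t j = 0; j < cols.size(); ++j) {
    double d = A(a, cols[j]) - B(b, cols[j]);
    s += d * d;
  }
  return s;
}

struct Neigh {
  double d2;
  int id;   // tie-break identifier (stable under row permutation)
  int lab;  // 0-based label code
};

static inline bool neigh_less(const Neigh &x, const Neigh &y) {
  if (x.d2 != y.d2) return x.d2 < y.d2;
  return x.id < y.id;
}

// Majority label among the first k entries of neigh; ties go to the smallest
// label code (canonical label order).
static inline int majority_of_k(std::vector<Neigh> &neigh, int k, int nlev) {
  std::partial_sort(neigh.begin(), neigh.begin() + k, neigh.end(), neigh_less);
  std::vector<int> cnt(nlev, 0);
  for (int i = 0; i < k; ++i) cnt[neigh[i].lab]++;
  int best = 0;
  for (int l = 1; l < nlev; ++l)
    if (cnt[l] > cnt[best]) best = l;
  return best;
}

// [[Rcpp::export(name = ".knn_predict_cpp")]]
IntegerVector knn_predict_cpp(NumericMatrix base_X, IntegerVector base_y,
                              NumericMatrix query_X, int k,
                              IntegerVector cols, int nlev,
                              IntegerVector base_ids) {
  int nb = base_X.nrow(), nq = query_X.nrow();
  std::vector<int> cc(cols.begin(), cols.end());
  IntegerVector out(nq);
  std::vector<Neigh> neigh(nb);
  for (int q = 0; q < nq; ++q) {
    for (int b = 0; b < nb; ++b) {
      neigh[b].d2 = dist2(query_X, q, base_X, b, cc);
      neigh[b].id = base_ids[b];
      neigh[b].lab = base_y[b];
    }
    out[q] = majority_of_k(neigh, k, nlev);
  }
  return out;
}

// Accuracy of r base KNN classifiers for support computation. Each row i of
// `subsets` holds the m 0-based feature columns of classifier i; row i of
// `base_idx` holds its nb 0-based base-sample rows. Query rows are the
// complement. Returns the fraction of query samples classified correctly by
// each base classifier.
// [[Rcpp::export(name = ".support_acc_cpp")]]
NumericVector support_acc_cpp(NumericMatrix X, IntegerVector y,
                              IntegerMatrix subsets, IntegerMatrix base_idx,
                              int k, int nlev) {
  int n = X.nrow();
  int r = subsets.nrow(), m = subsets.ncol(), nb = base_idx.ncol();
  int nq = n - nb;
  NumericVector acc(r);
  std::vector<int> cc(m);
  std::vector<char> in_base(n);
  std::vector<int> brows(nb), qrows(nq);
  std::vector<Neigh> neigh(nb);
  for (int i = 0; i < r; ++i) {
    for (int j = 0; j < m; ++j) cc[j] = subsets(i, j);
    std::fill(in_base.begin(), in_base.end(), 0);
    for (int j = 0; j < nb; ++j) {
      brows[j] = base_idx(i, j);
      in_base[brows[j]] = 1;
    }
    int t = 0;
    for (int s = 0; s < n; ++s)
      if (!in_base[s]) qrows[t++] = s;
    int correct = 0;
    for (int qi = 0; qi < nq; ++qi) {
      int q = qrows[qi];
      for (int b = 0; b < nb; ++b) {
        neigh[b].d2 = dist2(X, q, X, brows[b], cc);
        neigh[b].id = brows[b];
        neigh[b].lab = y[brows[b]];
      }
      if (majority_of_k(neigh, k, nlev) == y[q]) correct++;
    }
    acc[i] = nq > 0 ? (double)correct / nq : NA_REAL;
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return acc;
}

// Ensemble prediction: every base classifier uses the full training set as
// its neighbour pool; the final label is the majority over the r base votes,
// ties to the smallest label code.
// [[Rcpp::export(name = ".rknn_votes_cpp")]]
IntegerVector rknn_votes_cpp(NumericMatrix train_X, IntegerVector y,
                             NumericMatrix query_X, IntegerMatrix subsets,
                             int k, int nlev) {
  int n = train_X.nrow(), nq = query_X.nrow();
  int r = subsets.nrow(), m = subsets.ncol();
  IntegerVector out(nq);
  std::vector<int> cc(m);
  std::vector<Neigh> neigh(n);
  std::vector<int> votes(nlev);
  for (int q = 0; q < nq; ++q) {
    std::fill(votes.begin(), votes.end(), 0);
    for (int i = 0; i < r; ++i) {
      for (int j = 0; j < m; ++j) cc[j] = subsets(i, j);
      for (int b = 0; b < n; ++b) {
        neigh[b].d2 = dist2(query_X, q, train_X, b, cc);
        neigh[b].id = b;
        neigh[b].lab = y[b];
      }
      votes[majority_of_k(neigh, k, nlev)]++;
    }
    int best = 0;
    for (int l = 1; l < nlev; ++l)
      if (votes[l] > votes[best]) best = l;
    out[q] = best;
    Rcpp::checkUserInterrupt();
  }
  return out;
}
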