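#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Mendelian sampling variance of animal i given parental inbreeding.
// Unknown parents are treated as unique non-inbred founders.
static inline double mendelian_var(int s, int d, const NumericVector &F) {
  if (s >= 0 && d >= 0) return 0.5 - 0.25 * (F[s] + F[d]);
  if (s >= 0) return 0.75 - 0.25 * F[s];
  if (d >= 0) return 0.75 - 0.25 * F[d];
  return 1.0;
}

// Meuwissen & Luo tabular algorithm for inbreeding coefficients.
//
// sire, dam: 1-based parent indices into a topologically sorted pedigree
// (every parent precedes its offspring), 0 for unknown. Per-animal cost is
// bounded by the size of its ancestor set: for each animal the additive
// contributions L of its ancestors are accumulated youngest-first and
// A_ii = sum_j L_j^2 D_j, F_i = A_ii - 1.
// [[Rcpp::export(name = ".ml_inbreeding_cpp")]]
NumericVector ml_inbreeding_cpp(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericVector F(n);
  std::vector<double> D(n), L(n, 0.0);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i] - 1, d = dam[i] - 1;
    if (s >= i || d >= i)
      stop("pedigree is not topologically sorted at position %d", i + 1);
    D[i] = mendelian_var(s, d, F);
    if (s < 0 || d < 0) { F[i] = 0.0; continue; }
    // accumulate ancestor contributions, youngest (largest index) first
    std::priority_queue<int> pq;
    L[i] = 1.0;
    pq.push(i);
    double aii = 0.0;
    while (!pq.empty()) {
      const int j = pq.top();
      pq.pop();
      const double lj = L[j];
      if (lj == 0.0) continue;  // duplicate queue entry, already consumed
      L[j] = 0.0;
      aii += lj * lj * D[j];
      const int sj = sire[j] - 1, dj = dam[j] - 1;
      if (sj >= 0) { if (L[sj] == 0.0) pq.push(sj); L[sj] += 0.5 * lj; }
      if (dj >= 0) { if (L[dj] == 0.0) pq.push(dj); L[dj] += 0.5 * lj; }
    }
    F[i] = aii - 1.0;
  }
  return F;
}

// Indirect product w = A x of the additive (numerator) relationship matrix
// with a vector, without forming A (Colleau-style two-sweep using
// A = T D T'). O(n) per call; used for pairwise kinship and cohort mean
// kinship. F must hold the inbreeding coefficients of the same pedigree.
// [[Rcpp::export(name = ".relationship_Ax_cpp")]]
NumericVector relationship_Ax_cpp(IntegerVector sire, IntegerVector dam,
                                  NumericVector F, NumericVector x) {
  const int n = sire.size();
  if (F.size() != n || x.size() != n)
    stop("lengths of sire, dam, F and x must agree");
  std::vector<double> b(x.begin(), x.end());
  for (int i = n - 1; i >= 0; --i) {     // b = T' x (descendant sweep)
    const double bi = b[i];
    if (bi == 0.0) continue;
    if (sire[i] > 0) b[sire[i] - 1] += 0.5 * bi;
    if (dam[i] > 0)  b[dam[i] - 1]  += 0.5 * bi;
  }
  NumericVector w(n);                    // w = T (D b) (ancestor sweep)
  for (int i = 0; i < n; ++i) {
    const int s = sire[i] - 1, d = dam[i] - 1;
    double wi = mendelian_var(s, d, F) * b[i];
    if (s >= 0) wi += 0.5 * w[s];
    if (d >= 0) wi += 0.5 * w[d];
    w[i] = wi;
  }
  return w;
}
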