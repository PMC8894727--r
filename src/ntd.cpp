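#include <Rcpp.h>
using namespace Rcpp;

// Nearest-taxon distances for every (feature, sample) pair under a tip-label
// permutation of the cophenetic matrix. Permuting tip labels is applied as
// D_perm[a, b] = D[perm[a], perm[b]]; presence/abundance is never permuted.
//
// D        : F x F cophenetic distance matrix (tips in table order)
// presence : F x S logical matrix, presence[a, j] = feature a present in j
// perm     : length-F 1-based permutation (identity gives the observed value)
// allow_conspecifics : if false, the feature itself is excluded from the
//                      minimum when it is present in the comparison sample
//
// Returns an F x S matrix; entry is NA when sample j offers no comparison
// feature (empty sample, or j = {a} alone under conspecific exclusion).
// [[Rcpp::export]]
NumericMatrix ntd_matrix_cpp(const NumericMatrix& D,
                             const LogicalMatrix& presence,
                             const IntegerVector& perm,
                             bool allow_conspecifics) {
  const int F = D.nrow(), S = presence.ncol();
  NumericMatrix out(F, S);

  // cache per-sample member indices
  std::vector< std::vector<int> > members(S);
  for (int j = 0; j < S; ++j) {
    for (int b = 0; b < F; ++b)
      if (presence(b, j)) members[j].push_back(b);
  }

  for (int j = 0; j < S; ++j) {
    const std::vector<int>& mem = members[j];
    for (int a = 0; a < F; ++a) {
      const int pa = perm[a] - 1;
      double best = R_PosInf;
      for (size_t k = 0; k < mem.size(); ++k) {
        const int b = mem[k];
        if (!allow_conspecifics && b == a) continue;
        const double d = D(pa, perm[b] - 1);
        if (d < best) best = d;
      }
      out(a, j) = R_FINITE(best) ? best : NA_REAL;
    }
  }
  return out;
}

// Null beta-MNTD_feat accumulation over a set of permutations: for each
// permutation r and feature a, the mean of ntd over the scope samples
// (columns of `presence`), before abundance weighting and noise.
// perms: R x F matrix of 1-based permutations.
// Returns R x F matrix of per-replicate scope-mean nearest-taxon distances;
// NA-propagating (a sample with no comparison feature yields NA).
// [[Rcpp::export]]
NumericMatrix null_scope_means_cpp(const NumericMatrix& D,
                                   const LogicalMatrix& presence,
                                   const IntegerMatrix& perms,
                                   bool allow_conspecifics) {
  const int F = D.nrow(), S = presence.ncol(), R = perms.nrow();
  NumericMatrix out(R, F);

  std::vector< std::vector<int> > members(S);
  for (int j = 0; j < S; ++j)
    for (int b = 0; b < F; ++b)
      if (presence(b, j)) members[j].push_back(b);

  for (int r = 0; r < R; ++r) {
    for (int a = 0; a < F; ++a) {
      const int pa = perms(r, a) - 1;
      double acc = 0.0;
      bool na = false;
      for (int j = 0; j < S; ++j) {
        const std::vector<int>& mem = members[j];
        double best = R_PosInf;
        for (size_t k = 0; k < mem.size(); ++k) {
          const int b = mem[k];
          if (!allow_conspecifics && b == a) continue;
          const double d = D(pa, perms(r, b) - 1);
          if (d < best) best = d;
        }
        if (!R_FINITE(best)) { na = true; break; }
        acc += best;
      }
      out(r, a) = na ? NA_REAL : acc / S;
    }
  }
  return out;
}
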