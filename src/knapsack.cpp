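#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Unbounded-knapsack reachability over discretised residue masses.
// Bin b is set iff some multiset of the vocabulary residue masses sums
// (after rounding each mass to the nearest bin) into bin b. Bin 0 (the
// empty multiset) is always set; feasibility is closed under adding any
// residue mass while it stays below max_mass.
// [[Rcpp::export]]
LogicalVector knapsack_reachable_cpp(NumericVector masses, double resolution,
                                     double max_mass) {
  if (resolution <= 0 || max_mass <= 0)
    stop("resolution and max_mass must be positive");
  const R_xlen_t n = (R_xlen_t)std::floor(max_mass / resolution + 0.5) + 1;
  std::vector<long long> mbin;
  mbin.reserve(masses.size());
  for (R_xlen_t i = 0; i < masses.size(); ++i) {
    long long mb = (long long)std::llround(masses[i] / resolution);
    if (mb <= 0) stop("residue mass rounds to a non-positive bin");
    mbin.push_back(mb);
  }
  std::vector<char> feas((size_t)n, 0);
  feas[0] = 1;
  for (R_xlen_t b = 0; b < n; ++b) {
    if (!feas[(size_t)b]) continue;
    for (size_t k = 0; k < mbin.size(); ++k) {
      const long long nb = b + mbin[k];
      if (nb < n) feas[(size_t)nb] = 1;
    }
  }
  LogicalVector out(n);
  for (R_xlen_t b = 0; b < n; ++b) out[b] = feas[(size_t)b] != 0;
  return out;
}
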