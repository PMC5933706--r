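#include <Rcpp.h>
using namespace Rcpp;

// Extended haplotype homozygosity over every column, relative to a core
// column (1-based). ehh[j] = fraction of row pairs identical over all
// columns between core and j inclusive. Computed by outward partition
// refinement in both directions.
// [[Rcpp::export]]
NumericVector ehh_curve_cpp(IntegerMatrix alleles, int core) {
  const int n = alleles.nrow(), m = alleles.ncol();
  const int c0 = core - 1;
  NumericVector ehh(m, NA_REAL);
  if (n < 2) return ehh;
  const double denom = n * (n - 1.0) / 2.0;

  std::vector<int> grp(n), ng(n);
  for (int dir = 0; dir < 2; ++dir) {
    std::fill(grp.begin(), grp.end(), 0);
    int ngroups = 1;
    for (int j = c0; dir == 0 ? j < m : j >= 0; dir == 0 ? ++j : --j) {
      // refine partition by allele at column j: new group id = 2*old + allele
      std::map<std::pair<int, int>, int> remap;
      int next = 0;
      for (int i = 0; i < n; ++i) {
        std::pair<int, int> key(grp[i], alleles(i, j));
        auto it = remap.find(key);
        if (it == remap.end()) {
          remap[key] = next;
          ng[i] = next++;
        } else ng[i] = it->second;
      }
      std::swap(grp, ng);
      ngroups = next;
      std::vector<double> sz(ngroups, 0.0);
      for (int i = 0; i < n; ++i) sz[grp[i]] += 1.0;
      double hom = 0.0;
      for (int g = 0; g < ngroups; ++g) hom += sz[g] * (sz[g] - 1.0) / 2.0;
      ehh[j] = hom / denom;
      if (ngroups == n) {  // fully resolved: EHH is 0 beyond this point
        if (dir == 0) for (int k = j + 1; k < m; ++k) ehh[k] = 0.0;
        else for (int k = j - 1; k >= 0; --k) ehh[k] = 0.0;
        break;
      }
    }
  }
  return ehh;
}
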