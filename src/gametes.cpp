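#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Meiosis under a Haldane (no-interference) map: crossover count per
// chromosome is Poisson(length in Morgans), positions uniform.
//
// H holds phased haplotypes as rows: individual i (0-based) owns rows 2i and
// 2i + 1. `parent` gives, per requested gamete, the 0-based index of the
// individual producing it. `pos` is the within-chromosome position in
// Morgans; loci must be grouped by chromosome and sorted by position within
// each block. Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix drop_gametes_cpp(const IntegerMatrix& H,
                               const IntegerVector& parent,
                               const NumericVector& pos,
                               const IntegerVector& chr) {
  const int m = H.ncol();
  const int ng = parent.size();
  if (pos.size() != m || chr.size() != m)
    stop("map length does not match haplotype columns");
  IntegerMatrix out(ng, m);

  // chromosome block boundaries
  std::vector<int> starts, ends;
  int j = 0;
  while (j < m) {
    int c = chr[j], s = j;
    while (j < m && chr[j] == c) ++j;
    starts.push_back(s);
    ends.push_back(j);
  }

  std::vector<double> xo;
  for (int g = 0; g < ng; ++g) {
    int p = parent[g];
    if (p < 0 || 2 * p + 1 >= H.nrow()) stop("parent index out of range");
    const int h0 = 2 * p, h1 = 2 * p + 1;
    for (size_t b = 0; b < starts.size(); ++b) {
      const int s = starts[b], e = ends[b];
      const double lo = pos[s], len = pos[e - 1] - pos[s];
      int phase = (unif_rand() < 0.5) ? 0 : 1;
      int nxo = (len > 0.0) ? (int)R::rpois(len) : 0;
      xo.clear();
      for (int k = 0; k < nxo; ++k) xo.push_back(lo + unif_rand() * len);
      std::sort(xo.begin(), xo.end());
      size_t nxt = 0;
      for (int l = s; l < e; ++l) {
        while (nxt < xo.size() && xo[nxt] <= pos[l]) { phase ^= 1; ++nxt; }
        out(g, l) = (phase == 0) ? H(h0, l) : H(h1, l);
      }
    }
  }
  return out;
}
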