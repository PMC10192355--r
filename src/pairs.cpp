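#include <Rcpp.h>
#include "neighbors.h"
using namespace Rcpp;

// Unordered pairs (i < j, 1-based) of points within `radius` (inclusive).
// [[Rcpp::export]]
IntegerMatrix cpp_radius_pairs(NumericMatrix pos, double radius) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n);
  std::vector<int> ids(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1); ids[i] = i;
  }
  SpatialHash hash;
  std::vector<int> out_i, out_j, nb;
  if (n > 0) {
    hash.build(x.data(), y.data(), ids, std::max(radius, 1e-9));
    for (int i = 0; i < n; ++i) {
      hash.query(x[i], y[i], radius, i, x.data(), y.data(), nb);
      for (size_t k = 0; k < nb.size(); ++k)
        if (nb[k] > i) { out_i.push_back(i + 1); out_j.push_back(nb[k] + 1); }
    }
  }
  IntegerMatrix res(out_i.size(), 2);
  for (size_t k = 0; k < out_i.size(); ++k) {
    res(k, 0) = out_i[k]; res(k, 1) = out_j[k];
  }
  return res;
}
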