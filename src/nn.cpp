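#include <Rcpp.h>
using namespace Rcpp;

// Exact nearest-neighbour match from each query row to the target cloud.
// Brute force; cloud sizes in this package (<= a few 10^4) keep this fast
// and avoid the memory blow-up of a full R distance matrix.
// [[Rcpp::export(name = ".nnMatchCpp")]]
List nnMatchCpp(NumericMatrix query, NumericMatrix target) {
  const int nq = query.nrow(), nt = target.nrow();
  IntegerVector idx(nq);
  NumericVector dist(nq);
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf;
    int bestj = 0;
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    for (int j = 0; j < nt; ++j) {
      const double dx = qx - target(j, 0);
      const double dy = qy - target(j, 1);
      const double dz = qz - target(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bestj = j; }
    }
    idx[i] = bestj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
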