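#include <Rcpp.h>
using namespace Rcpp;

// For each 3D point, the indices (1-based) and dot products of the two
// sites with the largest dot product. Points and sites are n x 3 / m x 3.
// Used for nearest-site Voronoi assignment and boundary-band tests; avoids
// materializing the full n x m dot-product matrix.
// [[Rcpp::export]]
List top2_dot(NumericMatrix points, NumericMatrix sites) {
  const int n = points.nrow();
  const int m = sites.nrow();
  IntegerVector i1(n), i2(n);
  NumericVector d1(n), d2(n);
  std::vector<double> sx(m), sy(m), sz(m);
  for (int j = 0; j < m; ++j) {
    sx[j] = sites(j, 0); sy[j] = sites(j, 1); sz[j] = sites(j, 2);
  }
  for (int i = 0; i < n; ++i) {
    const double px = points(i, 0), py = points(i, 1), pz = points(i, 2);
    double b1 = -2.0, b2 = -2.0;
    int j1 = 0, j2 = 0;
    for (int j = 0; j < m; ++j) {
      const double d = px * sx[j] + py * sy[j] + pz * sz[j];
      if (d > b1) {
        b2 = b1; j2 = j1;
        b1 = d; j1 = j;
      } else if (d > b2) {
        b2 = d; j2 = j;
      }
    }
    i1[i] = j1 + 1; i2[i] = j2 + 1;
    d1[i] = b1; d2[i] = b2;
  }
  return List::create(_["i1"] = i1, _["i2"] = i2,
                      _["d1"] = d1, _["d2"] = d2);
}
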