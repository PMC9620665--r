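#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Mean local clustering coefficient of the radius graph over a 2-D point
// cloud, evaluated at each radius in r_px. Edge rule is strict Euclidean
// distance < r (compared on squared distances, so exact ties are non-edges).
// Adjacency is held as packed 64-bit rows; neighbor-pair connectivity is
// counted with popcounts, giving O(n^2 * n/64) per radius, which keeps the
// 50-value default sweep cheap for slides with up to a few thousand NFTs.
//
// exclude_low_degree: when false (default convention) nodes with degree < 2
// contribute a local coefficient of 0 to the mean; when true they are left
// out of the averaging entirely.
// [[Rcpp::export]]
NumericVector cc_sweep_cpp(NumericMatrix pts, NumericVector r_px,
                           bool exclude_low_degree) {
  const int n = pts.nrow();
  const int nr = r_px.size();
  NumericVector out(nr);
  if (n < 3) {
    std::fill(out.begin(), out.end(), NA_REAL);
    return out;
  }
  std::vector<double> d2(static_cast<size_t>(n) * n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      const double dx = pts(i, 0) - pts(j, 0);
      const double dy = pts(i, 1) - pts(j, 1);
      d2[static_cast<size_t>(i) * n + j] = dx * dx + dy * dy;
    }
  }
  const int words = (n + 63) / 64;
  std::vector<uint64_t> adj(static_cast<size_t>(n) * words);
  std::vector<int> deg(n);
  for (int t = 0; t < nr; ++t) {
    const double r2 = r_px[t] * r_px[t];
    std::fill(adj.begin(), adj.end(), 0ULL);
    std::fill(deg.begin(), deg.end(), 0);
    for (int i = 0; i < n; ++i) {
      uint64_t* row = &adj[static_cast<size_t>(i) * words];
      const double* di = &d2[static_cast<size_t>(i) * n];
      for (int j = 0; j < n; ++j) {
        if (i != j && di[j] < r2) {
          row[j >> 6] |= (1ULL << (j & 63));
          ++deg[i];
        }
      }
    }
    double sum = 0.0;
    int m = 0;
    for (int i = 0; i < n; ++i) {
      if (deg[i] >= 2) {
        // paired counts: sum over j in N(i) of |N(i) & N(j)| = 2 * triangles
        long long paired = 0;
        const uint64_t* ri = &adj[static_cast<size_t>(i) * words];
        for (int j = 0; j < n; ++j) {
          if ((ri[j >> 6] >> (j & 63)) & 1ULL) {
            const uint64_t* rj = &adj[static_cast<size_t>(j) * words];
            for (int w = 0; w < words; ++w) {
#if defined(__GNUC__) || defined(__clang__)
              paired += __builtin_popcountll(ri[w] & rj[w]);
#else
              uint64_t v = ri[w] & rj[w];
              while (v) { v &= v - 1; ++paired; }
#endif
            }
          }
        }
        sum += static_cast<double>(paired) /
               (static_cast<double>(deg[i]) * (deg[i] - 1));
        ++m;
      } else if (!exclude_low_degree) {
        ++m;
      }
    }
    out[t] = (m > 0) ? sum / m : NA_REAL;
  }
  return out;
}
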