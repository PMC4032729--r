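#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Region growing under the tolerance-of-similarity relation: starting from a
// seed pixel, repeatedly admit any 8-neighbor whose RGB Euclidean distance to
// the pixel it is reached from is <= tol (chained pairwise similarity).  The
// result is the connected component of the pixel graph whose edges join
// adjacent similar pixels, so it is independent of traversal order.
// seedRow/seedCol are 0-based.

// [[Rcpp::export]]
LogicalMatrix cpp_grow_region(const IntegerMatrix& r, const IntegerMatrix& g,
                              const IntegerMatrix& b,
                              int seedRow, int seedCol, double tol) {
  const int H = r.nrow(), W = r.ncol();
  if (seedRow < 0 || seedRow >= H || seedCol < 0 || seedCol >= W)
    stop("seed out of image bounds");
  LogicalMatrix mask(H, W);
  std::vector<int> frontier;
  frontier.reserve(4096);
  mask(seedRow, seedCol) = true;
  frontier.push_back(seedRow + seedCol * H);
  const double tol2 = tol * tol;
  while (!frontier.empty()) {
    const int idx = frontier.back();
    frontier.pop_back();
    const int row = idx % H, col = idx / H;
    const double pr = r(row, col), pg = g(row, col), pb = b(row, col);
    for (int dc = -1; dc <= 1; ++dc) {
      const int cc = col + dc;
      if (cc < 0 || cc >= W) continue;
      for (int dr = -1; dr <= 1; ++dr) {
        if (dr == 0 && dc == 0) continue;
        const int rr = row + dr;
        if (rr < 0 || rr >= H) continue;
        if (mask(rr, cc)) continue;
        const double d1 = r(rr, cc) - pr;
        const double d2 = g(rr, cc) - pg;
        const double d3 = b(rr, cc) - pb;
        if (d1 * d1 + d2 * d2 + d3 * d3 <= tol2) {
          mask(rr, cc) = true;
          frontier.push_back(rr + cc * H);
        }
      }
    }
  }
  return mask;
}
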