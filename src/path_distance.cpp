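// Multi-source Dijkstra over the 8-connected raster lattice with
// surface-length step costs: sqrt(h^2 + dz^2), h = cellSize for rook moves
// and cellSize * sqrt(2) for diagonal moves. NA elevation cells are
// impassable barriers; unreachable cells stay NA in the output.
#include <Rcpp.h>
#include <queue>
#include <tuple>
#include <vector>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export(name = ".dijkstraGrid")]]
NumericMatrix dijkstraGrid(NumericMatrix dem, IntegerMatrix sources,
                           double cellSize) {
  const int nr = dem.nrow(), nc = dem.ncol();
  const double INF = R_PosInf;
  std::vector<double> dist((size_t)nr * nc, INF);
  NumericMatrix out(nr, nc);

  // (distance, row, col): ties broken by (distance, row, col) order,
  // though the result is order-independent for non-negative weights.
  typedef std::tuple<double, int, int> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;

  int nSources = 0;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if (sources(r, c) == 1 && !NumericMatrix::is_na(dem(r, c))) {
        dist[(size_t)c * nr + r] = 0.0;
        pq.push(Node(0.0, r, c));
        ++nSources;
      }
  if (nSources == 0)
    stop("no source cells on passable elevation: at least one source cell "
         "must lie on a non-nodata DEM cell");

  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const double diag = cellSize * std::sqrt(2.0);

  while (!pq.empty()) {
    Node top = pq.top(); pq.pop();
    double d = std::get<0>(top);
    int r = std::get<1>(top), c = std::get<2>(top);
    if (d > dist[(size_t)c * nr + r]) continue; // stale entry
    double z = dem(r, c);
    for (int k = 0; k < 8; ++k) {
      int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      double z2 = dem(r2, c2);
      if (NumericMatrix::is_na(z2)) continue;
      double h = (dr[k] != 0 && dc[k] != 0) ? diag : cellSize;
      double dz = z2 - z;
      double nd = d + std::sqrt(h * h + dz * dz);
      size_t idx = (size_t)c2 * nr + r2;
      if (nd < dist[idx]) {
        dist[idx] = nd;
        pq.push(Node(nd, r2, c2));
      }
    }
  }

  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      double d = dist[(size_t)c * nr + r];
      out(r, c) = (d == INF) ? NA_REAL : d;
    }
  return out;
}
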