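#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Multi-source Dijkstra on the 26-connected voxel graph restricted to a
// binary mask. Edge weight between neighbouring voxels is the Euclidean
// step length in physical units (per-axis spacing in mm). Voxels outside
// the mask, and mask voxels unreachable from the sources, keep +Inf.
//
// mask    : logical vector of length prod(dim), column-major (R layout)
// dim     : integer(3) grid dimensions
// sources : 1-based linear indices of source voxels (must lie in the mask)
// spacing : numeric(3) physical voxel size per axis
// [[Rcpp::export]]
NumericVector cpp_geodesic(LogicalVector mask, IntegerVector dim,
                           IntegerVector sources, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");

  NumericVector dist(n, R_PosInf);

  // 26-neighbourhood offsets with physical step lengths
  std::vector<int> ox, oy, oz;
  std::vector<double> w;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
        double sx = dx * spacing[0], sy = dy * spacing[1], sz = dz * spacing[2];
        w.push_back(std::sqrt(sx * sx + sy * sy + sz * sz));
      }

  typedef std::pair<double, R_xlen_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;

  for (int s = 0; s < sources.size(); ++s) {
    R_xlen_t idx = (R_xlen_t)sources[s] - 1;
    if (idx < 0 || idx >= n) stop("source index out of range");
    if (!mask[idx]) stop("source voxel lies outside the mask");
    dist[idx] = 0.0;
    pq.push(QE(0.0, idx));
  }

  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    double d = top.first;
    R_xlen_t u = top.second;
    if (d > dist[u]) continue;  // stale entry
    int z = (int)(u / nxy);
    R_xlen_t rem = u % nxy;
    int y = (int)(rem / nx);
    int x = (int)(rem % nx);
    for (size_t k = 0; k < w.size(); ++k) {
      int xx = x + ox[k], yy = y + oy[k], zz = z + oz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      R_xlen_t v = (R_xlen_t)zz * nxy + (R_xlen_t)yy * nx + xx;
      if (!mask[v]) continue;
      double nd = d + w[k];
      if (nd < dist[v]) {
        dist[v] = nd;
        pq.push(QE(nd, v));
      }
    }
  }
  return dist;
}
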