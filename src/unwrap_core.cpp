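#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Flood-fill phase integration for branch-cut unwrapping.
// Starts at seed (0-based linear index, column-major), adds wrapped
// neighbour differences in BFS order, and never enters pixels marked as
// branch cuts. Returns the unwrapped surface and the reached mask.
// [[Rcpp::export(name = ".bfs_unwrap")]]
List bfs_unwrap(NumericMatrix wrapped, LogicalMatrix cut, int seed) {
  const int nr = wrapped.nrow(), nc = wrapped.ncol();
  NumericMatrix out(nr, nc);
  LogicalMatrix visited(nr, nc);
  const double TWO_PI = 2.0 * M_PI;
  if (seed < 0 || seed >= nr * nc) stop("seed index out of range");
  int si = seed % nr, sj = seed / nr;
  if (cut(si, sj)) stop("unwrap failed: seed pixel lies on a branch cut");
  std::queue<int> q;
  visited(si, sj) = true;
  out(si, sj) = wrapped(si, sj);
  q.push(seed);
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    int idx = q.front(); q.pop();
    int i = idx % nr, j = idx / nr;
    double v = out(i, j);
    for (int k = 0; k < 4; ++k) {
      int ni = i + di[k], nj = j + dj[k];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      if (visited(ni, nj) || cut(ni, nj)) continue;
      double d = wrapped(ni, nj) - wrapped(i, j);
      d -= TWO_PI * std::floor((d + M_PI) / TWO_PI); // wrap to (-pi, pi]
      if (d <= -M_PI) d += TWO_PI;
      visited(ni, nj) = true;
      out(ni, nj) = v + d;
      q.push(ni + nj * nr);
    }
  }
  return List::create(_["unwrapped"] = out, _["valid"] = visited);
}
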