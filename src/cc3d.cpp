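// 3D connected-component labelling, 6-neighbourhood, BFS.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".labelComponents3d")]]
IntegerVector labelComponents3d(LogicalVector mask) {
  IntegerVector d = mask.attr("dim");
  const int X = d[0], Y = d[1], Z = d[2];
  IntegerVector lab((size_t)X * Y * Z);
  lab.attr("dim") = d;
  int cur = 0;
  std::vector<size_t> queue;
  for (size_t s = 0; s < (size_t)X * Y * Z; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    queue.clear();
    queue.push_back(s);
    lab[s] = cur;
    while (!queue.empty()) {
      size_t v = queue.back();
      queue.pop_back();
      const int x = v % X, y = (v / X) % Y, z = v / ((size_t)X * Y);
      const int nx[6] = {x - 1, x + 1, x, x, x, x};
      const int ny[6] = {y, y, y - 1, y + 1, y, y};
      const int nz[6] = {z, z, z, z, z - 1, z + 1};
      for (int q = 0; q < 6; ++q) {
        if (nx[q] < 0 || nx[q] >= X || ny[q] < 0 || ny[q] >= Y || nz[q] < 0 ||
            nz[q] >= Z)
          continue;
        const size_t w = (size_t)nx[q] + (size_t)X * (ny[q] + (size_t)Y * nz[q]);
        if (mask[w] && lab[w] == 0) {
          lab[w] = cur;
          queue.push_back(w);
        }
      }
    }
  }
  return lab;
}
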