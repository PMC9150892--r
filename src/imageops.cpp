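// 3D binary image operations on column-major arrays (R layout).
// Voxels are addressed as i + nx*(j + ny*k), 0-based.
#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, nz;
  Grid(IntegerVector dims) : nx(dims[0]), ny(dims[1]), nz(dims[2]) {}
  inline bool inside(int x, int y, int z) const {
    return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
  }
  inline int idx(int x, int y, int z) const { return x + nx * (y + ny * z); }
  inline int size() const { return nx * ny * nz; }
};

// neighbour offsets for 6/18/26 connectivity
void neighbour_offsets(int connectivity, std::vector<int>& dx,
                       std::vector<int>& dy, std::vector<int>& dz) {
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (m == 0) continue;
        if ((connectivity == 6 && m > 1) || (connectivity == 18 && m > 2))
          continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
}

} // namespace

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  Grid g(dims);
  std::vector<int> dx, dy, dz;
  neighbour_offsets(connectivity, dx, dy, dz);
  IntegerVector labels(g.size(), 0);
  int next = 0;
  std::vector<int> stack;
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y)
      for (int x = 0; x < g.nx; ++x) {
        int v = g.idx(x, y, z);
        if (!mask[v] || labels[v]) continue;
        labels[v] = ++next;
        stack.clear();
        stack.push_back(v);
        while (!stack.empty()) {
          int cur = stack.back(); stack.pop_back();
          int cx = cur % g.nx, cy = (cur / g.nx) % g.ny, cz = cur / (g.nx * g.ny);
          for (size_t n = 0; n < dx.size(); ++n) {
            int px = cx + dx[n], py = cy + dy[n], pz = cz + dz[n];
            if (!g.inside(px, py, pz)) continue;
            int p = g.idx(px, py, pz);
            if (mask[p] && !labels[p]) { labels[p] = next; stack.push_back(p); }
          }
        }
      }
  labels.attr("n_components") = next;
  return labels;
}

// [[Rcpp::export(name = ".region_grow_cpp")]]
LogicalVector region_grow_cpp(NumericVector intensity, IntegerVector dims,
                              LogicalVector seed, double threshold,
                              int connectivity) {
  Grid g(dims);
  std::vector<int> dx, dy, dz;
  neighbour_offsets(connectivity, dx, dy, dz);
  LogicalVector out(g.size(), false);
  std::vector<int> stack;
  for (int v = 0; v < g.size(); ++v)
    if (seed[v]) { out[v] = true; stack.push_back(v); }
  while (!stack.empty()) {
    int cur = stack.back(); stack.pop_back();
    int cx = cur % g.nx, cy = (cur / g.nx) % g.ny, cz = cur / (g.nx * g.ny);
    for (size_t n = 0; n < dx.size(); ++n) {
      int px = cx + dx[n], py = cy + dy[n], pz = cz + dz[n];
      if (!g.inside(px, py, pz)) continue;
      int p = g.idx(px, py, pz);
      if (!out[p] && intensity[p] > threshold) { out[p] = true; stack.push_back(p); }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".dilate_cpp")]]
LogicalVector dilate_cpp(LogicalVector mask, IntegerVector dims,
                         int connectivity) {
  Grid g(dims);
  std::vector<int> dx, dy, dz;
  neighbour_offsets(connectivity, dx, dy, dz);
  LogicalVector out(clone(mask));
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y)
      for (int x = 0; x < g.nx; ++x) {
        int v = g.idx(x, y, z);
        if (!mask[v]) continue;
        for (size_t n = 0; n < dx.size(); ++n) {
          int px = x + dx[n], py = y + dy[n], pz = z + dz[n];
          if (g.inside(px, py, pz)) out[g.idx(px, py, pz)] = true;
        }
      }
  return out;
}

namespace {

// --- topology-preserving thinning -----------------------------------------
// A foreground voxel is "simple" (26/6 connectivity pair) when (a) the
// foreground restricted to its 26-neighbourhood forms exactly one
// 26-connected component and (b) the background restricted to its
// 18-neighbourhood forms exactly one 6-connected component containing a
// face neighbour. Removing a simple point does not change the topology.

// local 3x3x3 cube cell index: cx + 3*(cy + 3*cz), cells 0..26, centre 13
inline int cube_idx(int cx, int cy, int cz) { return cx + 3 * (cy + 3 * cz); }

int count_fg_components26(const bool nb[27]) {
  bool seen[27] = {false};
  int comps = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++comps;
    int top = 0;
    stack[top++] = s; seen[s] = true;
    while (top) {
      int cur = stack[--top];
      int x = cur % 3, y = (cur / 3) % 3, z = cur / 9;
      for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
          for (int c = -1; c <= 1; ++c) {
            int px = x + a, py = y + b, pz = z + c;
            if (px < 0 || px > 2 || py < 0 || py > 2 || pz < 0 || pz > 2)
              continue;
            int p = cube_idx(px, py, pz);
            if (p == 13 || p == cur || seen[p] || !nb[p]) continue;
            seen[p] = true; stack[top++] = p;
          }
    }
  }
  return comps;
}

int count_bg_components6(const bool nb[27]) {
  // cells of the 18-neighbourhood (distance-1 metric <= 2, not centre)
  bool in18[27];
  for (int s = 0; s < 27; ++s) {
    int x = s % 3, y = (s / 3) % 3, z = s / 9;
    int m = std::abs(x - 1) + std::abs(y - 1) + std::abs(z - 1);
    in18[s] = (m >= 1 && m <= 2);
  }
  bool seen[27] = {false};
  int comps = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (!in18[s] || nb[s] || seen[s]) continue;
    int x = s % 3, y = (s / 3) % 3, z = s / 9;
    // component must be seeded at (and therefore contain) a face neighbour
    if (std::abs(x - 1) + std::abs(y - 1) + std::abs(z - 1) != 1) continue;
    ++comps;
    int top = 0;
    stack[top++] = s; seen[s] = true;
    while (top) {
      int cur = stack[--top];
      int cx = cur % 3, cy = (cur / 3) % 3, cz = cur / 9;
      const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int n = 0; n < 6; ++n) {
        int px = cx + d6[n][0], py = cy + d6[n][1], pz = cz + d6[n][2];
        if (px < 0 || px > 2 || py < 0 || py > 2 || pz < 0 || pz > 2)
          continue;
        int p = cube_idx(px, py, pz);
        if (!in18[p] || nb[p] || seen[p]) continue;
        seen[p] = true; stack[top++] = p;
      }
    }
  }
  return comps;
}

void fill_neighbourhood(const std::vector<char>& mask, const Grid& g,
                        int x, int y, int z, bool nb[27]) {
  for (int c = 0; c < 3; ++c)
    for (int b = 0; b < 3; ++b)
      for (int a = 0; a < 3; ++a) {
        int px = x + a - 1, py = y + b - 1, pz = z + c - 1;
        nb[cube_idx(a, b, c)] =
          g.inside(px, py, pz) && mask[g.idx(px, py, pz)];
      }
}

inline int fg_neighbour_count(const bool nb[27]) {
  int n = 0;
  for (int s = 0; s < 27; ++s) if (s != 13 && nb[s]) ++n;
  return n;
}

inline bool is_simple(const bool nb[27]) {
  return count_fg_components26(nb) == 1 && count_bg_components6(nb) == 1;
}

} // namespace

// [[Rcpp::export(name = ".skeletonize_cpp")]]
LogicalVector skeletonize_cpp(LogicalVector mask, IntegerVector dims) {
  Grid g(dims);
  std::vector<char> cur(g.size());
  for (int v = 0; v < g.size(); ++v) cur[v] = mask[v] ? 1 : 0;
  const int dirs[6][3] = {{0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};
  bool nb[27];
  bool changed = true;
  std::vector<int> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int z = 0; z < g.nz; ++z)
        for (int y = 0; y < g.ny; ++y)
          for (int x = 0; x < g.nx; ++x) {
            int v = g.idx(x, y, z);
            if (!cur[v]) continue;
            int bx = x + dirs[d][0], by = y + dirs[d][1], bz = z + dirs[d][2];
            bool border = !g.inside(bx, by, bz) || !cur[g.idx(bx, by, bz)];
            if (!border) continue;
            fill_neighbourhood(cur, g, x, y, z, nb);
            if (fg_neighbour_count(nb) <= 1) continue; // line end: keep
            if (is_simple(nb)) cand.push_back(v);
          }
      // sequential re-check: earlier deletions may make later ones unsafe
      for (size_t i = 0; i < cand.size(); ++i) {
        int v = cand[i];
        int x = v % g.nx, y = (v / g.nx) % g.ny, z = v / (g.nx * g.ny);
        fill_neighbourhood(cur, g, x, y, z, nb);
        if (fg_neighbour_count(nb) <= 1) continue;
        if (is_simple(nb)) { cur[v] = 0; changed = true; }
      }
    }
  }
  LogicalVector out(g.size());
  for (int v = 0; v < g.size(); ++v) out[v] = cur[v] != 0;
  return out;
}
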