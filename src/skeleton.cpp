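#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

// 3x3x3 neighborhood cell index for offsets in {-1,0,1}^3
static inline int cell(int dz, int dy, int dx) {
  return (dz + 1) + 3 * (dy + 1) + 9 * (dx + 1);
}

// Simple-point test for 26-connected foreground / 6-connected background
// (topological numbers T26(x, FG) == 1 and T6(x, BG) == 1, the classical
// Bertrand-Malandain characterization). neigh[27]: foreground flags of the
// 3x3x3 neighborhood, center at cell(0,0,0) = 13.
static bool is_simple_point(const bool neigh[27]) {
  // T26: 26-connected foreground components among the 26 neighbors
  bool seen[27] = {false};
  int comp26 = 0;
  for (int c = 0; c < 27; ++c) {
    if (c == 13 || !neigh[c] || seen[c]) continue;
    ++comp26;
    if (comp26 > 1) return false;
    int stack[27], top = 0;
    stack[top++] = c; seen[c] = true;
    while (top) {
      int cur = stack[--top];
      int cz = cur % 3 - 1, cy = (cur / 3) % 3 - 1, cx = cur / 9 - 1;
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            int zz = cz + dz, yy = cy + dy, xx = cx + dx;
            if (zz < -1 || zz > 1 || yy < -1 || yy > 1 || xx < -1 || xx > 1)
              continue;
            int nc = cell(zz, yy, xx);
            if (nc == 13 || seen[nc] || !neigh[nc]) continue;
            seen[nc] = true; stack[top++] = nc;
          }
    }
  }
  if (comp26 != 1) return false;
  // T6: 6-connected background components within the 18-neighborhood that
  // touch a face neighbor of the center
  bool seenb[27] = {false};
  int comp6 = 0;
  for (int c = 0; c < 27; ++c) {
    int cz = c % 3 - 1, cy = (c / 3) % 3 - 1, cx = c / 9 - 1;
    int ad = std::abs(cz) + std::abs(cy) + std::abs(cx);
    if (ad != 1) continue; // seed only from face neighbors
    if (neigh[c] || seenb[c]) continue;
    ++comp6;
    if (comp6 > 1) return false;
    int stack[27], top = 0;
    stack[top++] = c; seenb[c] = true;
    while (top) {
      int cur = stack[--top];
      int uz = cur % 3 - 1, uy = (cur / 3) % 3 - 1, ux = cur / 9 - 1;
      const int face[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int f = 0; f < 6; ++f) {
        int zz = uz + face[f][0], yy = uy + face[f][1], xx = ux + face[f][2];
        if (zz < -1 || zz > 1 || yy < -1 || yy > 1 || xx < -1 || xx > 1) continue;
        int ad2 = std::abs(zz) + std::abs(yy) + std::abs(xx);
        if (ad2 > 2 || ad2 == 0) continue; // stay inside N18
        int nc = cell(zz, yy, xx);
        if (seenb[nc] || neigh[nc]) continue;
        seenb[nc] = true; stack[top++] = nc;
      }
    }
  }
  return comp6 == 1;
}

// Topology-preserving sequential 3D thinning. Simple points are removed in
// order of increasing priority (typically the Euclidean distance transform,
// which centers the skeleton), curve endpoints (<= 1 foreground neighbor)
// are retained. Foreground is 26-connected, background 6-connected.
// [[Rcpp::export]]
LogicalVector thin3d_cpp(LogicalVector mask, IntegerVector dims,
                         NumericVector priority) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const size_t n = (size_t)nz * ny * nx;
  std::vector<uint8_t> vol(n);
  for (size_t i = 0; i < n; ++i) vol[i] = mask[i] ? 1 : 0;

  auto fg = [&](int z, int y, int x) -> bool {
    if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) return false;
    return vol[z + (size_t)nz * (y + (size_t)ny * x)] != 0;
  };
  auto gather = [&](int z, int y, int x, bool neigh[27]) {
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz)
          neigh[cell(dz, dy, dx)] = fg(z + dz, y + dy, x + dx);
  };
  auto n26 = [&](const bool neigh[27]) {
    int c = 0;
    for (int i = 0; i < 27; ++i) if (i != 13 && neigh[i]) ++c;
    return c;
  };
  auto is_border = [&](int z, int y, int x) -> bool {
    return !fg(z + 1, y, x) || !fg(z - 1, y, x) || !fg(z, y + 1, x) ||
           !fg(z, y - 1, x) || !fg(z, y, x + 1) || !fg(z, y, x - 1);
  };

  // first pass scans the whole volume; later passes only revisit foreground
  // neighbors of freshly removed voxels (the only places whose border /
  // simple status can have changed) - semantics identical, much faster
  std::vector<size_t> cand, removed;
  std::vector<uint8_t> queued(n, 0);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        size_t i = z + (size_t)nz * (y + (size_t)ny * x);
        if (vol[i] && is_border(z, y, x)) cand.push_back(i);
      }
  while (!cand.empty()) {
    std::stable_sort(cand.begin(), cand.end(), [&](size_t a, size_t b) {
      if (priority[a] != priority[b]) return priority[a] < priority[b];
      return a < b;
    });
    removed.clear();
    for (size_t k = 0; k < cand.size(); ++k) {
      size_t i = cand[k];
      queued[i] = 0;
      if (!vol[i]) continue;
      int z = i % nz, y = (i / nz) % ny, x = i / ((size_t)nz * ny);
      if (!is_border(z, y, x)) continue;
      bool neigh[27];
      gather(z, y, x, neigh);
      if (n26(neigh) <= 1) continue; // curve endpoint
      if (!is_simple_point(neigh)) continue;
      vol[i] = 0;
      removed.push_back(i);
    }
    cand.clear();
    for (size_t rix = 0; rix < removed.size(); ++rix) {
      size_t i = removed[rix];
      int z = i % nz, y = (i / nz) % ny, x = i / ((size_t)nz * ny);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            int zz = z + dz, yy = y + dy, xx = x + dx;
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            size_t j = zz + (size_t)nz * (yy + (size_t)ny * xx);
            if (vol[j] && !queued[j]) { queued[j] = 1; cand.push_back(j); }
          }
    }
  }
  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = vol[i] != 0;
  return out;
}

// Decompose a thin skeleton into voxels, degrees and branch paths.
// Nodes are voxels with 26-degree != 2; branches are simple voxel paths
// between nodes (node voxels included at both ends); isolated 26-connected
// cycles become closed branches (first voxel repeated last); isolated voxels
// become single-point branches. Deterministic: voxels enumerated in array
// scan order (z fastest), neighbor directions in fixed offset order.
// [[Rcpp::export]]
List trace_graph_cpp(LogicalVector skel, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  // reject non-thin input: any fully occupied 2x2x2 block
  for (int x = 0; x + 1 < nx; ++x)
    for (int y = 0; y + 1 < ny; ++y)
      for (int z = 0; z + 1 < nz; ++z) {
        bool full = true;
        for (int dx = 0; dx <= 1 && full; ++dx)
          for (int dy = 0; dy <= 1 && full; ++dy)
            for (int dz = 0; dz <= 1 && full; ++dz)
              if (!skel[(z + dz) + (size_t)nz * ((y + dy) + (size_t)ny * (x + dx))])
                full = false;
        if (full)
          stop("skeleton is not thin: fully occupied 2x2x2 block at voxel (z=%d, y=%d, x=%d) [1-based]",
               z + 1, y + 1, x + 1);
      }

  std::vector<int> idmap((size_t)nz * ny * nx, -1);
  std::vector<int> vz, vy, vx;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        size_t i = z + (size_t)nz * (y + (size_t)ny * x);
        if (skel[i]) {
          idmap[i] = (int)vz.size();
          vz.push_back(z); vy.push_back(y); vx.push_back(x);
        }
      }
  const int nv = (int)vz.size();
  std::vector<std::vector<int>> nbr(nv);
  for (int id = 0; id < nv; ++id) {
    int z = vz[id], y = vy[id], x = vx[id];
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          if (dz == 0 && dy == 0 && dx == 0) continue;
          int zz = z + dz, yy = y + dy, xx = x + dx;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          int j = idmap[zz + (size_t)nz * (yy + (size_t)ny * xx)];
          if (j >= 0) nbr[id].push_back(j);
        }
  }
  std::unordered_set<uint64_t> evis;
  auto ekey = [&](int a, int b) -> uint64_t {
    if (a > b) std::swap(a, b);
    return (uint64_t)a * (uint64_t)nv + (uint64_t)b;
  };
  std::vector<std::vector<int>> branches;
  // branches incident to nodes
  for (int u = 0; u < nv; ++u) {
    if (nbr[u].size() == 2) continue; // not a node
    for (size_t d = 0; d < nbr[u].size(); ++d) {
      int v = nbr[u][d];
      if (evis.count(ekey(u, v))) continue;
      std::vector<int> path;
      path.push_back(u); path.push_back(v);
      evis.insert(ekey(u, v));
      int prev = u, cur = v;
      while (nbr[cur].size() == 2) {
        int nxt = (nbr[cur][0] == prev) ? nbr[cur][1] : nbr[cur][0];
        if (evis.count(ekey(cur, nxt))) break; // closed loop back into path
        evis.insert(ekey(cur, nxt));
        path.push_back(nxt);
        prev = cur; cur = nxt;
      }
      branches.push_back(path);
    }
  }
  // leftover pure cycles of degree-2 voxels
  for (int u = 0; u < nv; ++u) {
    if (nbr[u].size() != 2) continue;
    bool touched = false;
    for (int v : nbr[u]) if (evis.count(ekey(u, v))) { touched = true; break; }
    if (touched) continue;
    std::vector<int> path;
    path.push_back(u);
    int prev = u, cur = nbr[u][0];
    evis.insert(ekey(u, cur));
    path.push_back(cur);
    while (cur != u) {
      int nxt = (nbr[cur][0] == prev) ? nbr[cur][1] : nbr[cur][0];
      evis.insert(ekey(cur, nxt));
      path.push_back(nxt);
      prev = cur; cur = nxt;
    }
    branches.push_back(path);
  }
  // isolated voxels
  for (int u = 0; u < nv; ++u)
    if (nbr[u].empty()) branches.push_back(std::vector<int>(1, u));

  IntegerMatrix vox(nv, 3);
  IntegerVector degree(nv);
  for (int id = 0; id < nv; ++id) {
    vox(id, 0) = vz[id] + 1; vox(id, 1) = vy[id] + 1; vox(id, 2) = vx[id] + 1;
    degree[id] = (int)nbr[id].size();
  }
  List br(branches.size());
  for (size_t b = 0; b < branches.size(); ++b) {
    IntegerVector p(branches[b].size());
    for (size_t i = 0; i < branches[b].size(); ++i) p[i] = branches[b][i] + 1;
    br[b] = p;
  }
  return List::create(_["voxels"] = vox, _["degree"] = degree,
                      _["branches"] = br);
}
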