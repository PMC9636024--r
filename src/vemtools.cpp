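// Raster primitives for vemtools: connected components, ball morphology,
// union-find partitions and marching-tetrahedra iso-surfacing.
// Arrays arrive in R's column-major layout, axis order (x, y, z), x fastest.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <array>
#include <set>
#include <utility>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static std::vector<std::array<int, 3>> neighbor_offsets(int connectivity) {
  std::vector<std::array<int, 3>> off;
  if (connectivity == 4 || connectivity == 8) {
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0) continue;
        int m = std::abs(dx) + std::abs(dy);
        if (connectivity == 4 && m > 1) continue;
        off.push_back({dx, dy, 0});
      }
    return off;
  }
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        off.push_back({dx, dy, dz});
      }
  return off;
}

// Connected components of a binary mask. Labels 1..K assigned in raster-scan
// order of each component's first-encountered voxel.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  std::vector<std::array<int, 3>> off = neighbor_offsets(connectivity);
  IntegerVector out(n, 0);
  int next_label = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t idx = 0; idx < n; ++idx) {
    if (mask[idx] == 0 || out[idx] != 0) continue;
    ++next_label;
    out[idx] = next_label;
    q.push(idx);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int x = (int)(cur % nx);
      int y = (int)((cur / nx) % ny);
      int z = (int)(cur / ((R_xlen_t)nx * ny));
      for (const auto &d : off) {
        int xx = x + d[0], yy = y + d[1], zz = z + d[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t nb = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[nb] != 0 && out[nb] == 0) {
          out[nb] = next_label;
          q.push(nb);
        }
      }
    }
  }
  out.attr("n_components") = next_label;
  return out;
}

// Connected components of a label field: voxels are connected when adjacent
// under `connectivity` AND carrying the same nonzero value. Output labels
// 1..K in raster-scan order of each component's first voxel.
// [[Rcpp::export]]
IntegerVector cpp_label_components_multi(IntegerVector vals, IntegerVector dim,
                                         int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (vals.size() != n) stop("vals length does not match dim");
  std::vector<std::array<int, 3>> off = neighbor_offsets(connectivity);
  IntegerVector out(n, 0);
  int next_label = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t idx = 0; idx < n; ++idx) {
    if (vals[idx] == 0 || out[idx] != 0) continue;
    ++next_label;
    out[idx] = next_label;
    q.push(idx);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int x = (int)(cur % nx);
      int y = (int)((cur / nx) % ny);
      int z = (int)(cur / ((R_xlen_t)nx * ny));
      for (const auto &d : off) {
        int xx = x + d[0], yy = y + d[1], zz = z + d[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t nb = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (vals[nb] == vals[cur] && out[nb] == 0) {
          out[nb] = next_label;
          q.push(nb);
        }
      }
    }
  }
  out.attr("n_components") = next_label;
  return out;
}

static std::vector<std::array<int, 3>> ball_offsets(double radius,
                                                    NumericVector scale) {
  std::vector<std::array<int, 3>> off;
  if (radius < 0) stop("radius must be >= 0");
  int rx = (int)std::floor(radius / scale[0] + 1e-9);
  int ry = (int)std::floor(radius / scale[1] + 1e-9);
  int rz = (int)std::floor(radius / scale[2] + 1e-9);
  double r2 = radius * radius + 1e-9;
  for (int dz = -rz; dz <= rz; ++dz)
    for (int dy = -ry; dy <= ry; ++dy)
      for (int dx = -rx; dx <= rx; ++dx) {
        double d2 = dx * scale[0] * dx * scale[0] +
                    dy * scale[1] * dy * scale[1] +
                    dz * scale[2] * dz * scale[2];
        if (d2 <= r2) off.push_back({dx, dy, dz});
      }
  return off;
}

// Binary erosion/dilation with the digitized ball of given radius.
// scale = per-axis metric of one voxel step (1,1,1 for index-space balls,
// voxel_size for nm-metric balls). Outside the array counts as background.
// [[Rcpp::export]]
IntegerVector cpp_morph_ball(IntegerVector mask, IntegerVector dim,
                             double radius, NumericVector scale, bool dilate) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  std::vector<std::array<int, 3>> off = ball_offsets(radius, scale);
  IntegerVector out(n);
  for (R_xlen_t idx = 0; idx < n; ++idx) {
    int x = (int)(idx % nx);
    int y = (int)((idx / nx) % ny);
    int z = (int)(idx / ((R_xlen_t)nx * ny));
    int val = dilate ? 0 : 1;
    for (const auto &d : off) {
      int xx = x + d[0], yy = y + d[1], zz = z + d[2];
      int inside = (xx >= 0 && xx < nx && yy >= 0 && yy < ny &&
                    zz >= 0 && zz < nz);
      int v = inside ? (mask[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)] != 0)
                     : 0;
      if (dilate) { if (v) { val = 1; break; } }
      else        { if (!v) { val = 0; break; } }
    }
    out[idx] = val;
  }
  return out;
}

struct UF {
  std::vector<int> parent;
  UF(int n) : parent(n) { for (int i = 0; i < n; ++i) parent[i] = i; }
  int find(int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (a < b) parent[b] = a; else parent[a] = b;  // keep smallest index as root
  }
};

// Partition of nodes 1..n under undirected edges; returns, for every node,
// the smallest node index of its component.
// [[Rcpp::export]]
IntegerVector cpp_uf_partition(int n, IntegerVector ea, IntegerVector eb) {
  if (ea.size() != eb.size()) stop("edge vectors differ in length");
  UF uf(n);
  for (R_xlen_t i = 0; i < ea.size(); ++i) {
    int a = ea[i], b = eb[i];
    if (a < 1 || a > n || b < 1 || b > n) stop("edge endpoint out of range");
    uf.unite(a - 1, b - 1);
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = uf.find(i) + 1;
  return out;
}

// ---- marching tetrahedra ---------------------------------------------------
// Each grid cell (cube of 8 voxel centers) is split into 6 tetrahedra around
// the 0-7 diagonal; within a tetrahedron the iso-surface is one or two
// triangles with vertices linearly interpolated along crossing edges.

static const int TETRA[6][4] = {
  {0, 5, 1, 7}, {0, 1, 3, 7}, {0, 3, 2, 7},
  {0, 2, 6, 7}, {0, 6, 4, 7}, {0, 4, 5, 7}};

// corner index -> (dx,dy,dz) within cell
static const int CORNER[8][3] = {
  {0, 0, 0}, {1, 0, 0}, {0, 1, 0}, {1, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {0, 1, 1}, {1, 1, 1}};

// [[Rcpp::export]]
List cpp_marching_tetra(NumericVector field, IntegerVector dim, double iso,
                        NumericVector spacing, NumericVector origin) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  if (field.size() != (R_xlen_t)nx * ny * nz) stop("field length mismatch");
  std::vector<double> vx, vy, vz;
  auto val = [&](int x, int y, int z) -> double {
    return field[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
  };
  double cx[8], cy[8], cz[8], cv[8];
  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int xx = x + CORNER[c][0], yy = y + CORNER[c][1], zz = z + CORNER[c][2];
          cv[c] = val(xx, yy, zz);
          cx[c] = origin[0] + xx * spacing[0];
          cy[c] = origin[1] + yy * spacing[1];
          cz[c] = origin[2] + zz * spacing[2];
          if (cv[c] > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          const int *tc = TETRA[t];
          int inside[4], nin = 0, nout = 0;
          for (int k = 0; k < 4; ++k) {
            inside[k] = cv[tc[k]] > iso;
            if (inside[k]) ++nin; else ++nout;
          }
          if (nin == 0 || nout == 0) continue;
          // interpolated point on edge (a,b) of the tetrahedron
          auto emit = [&](int a, int b) {
            double va = cv[tc[a]], vb = cv[tc[b]];
            double tt = (iso - va) / (vb - va);
            vx.push_back(cx[tc[a]] + tt * (cx[tc[b]] - cx[tc[a]]));
            vy.push_back(cy[tc[a]] + tt * (cy[tc[b]] - cy[tc[a]]));
            vz.push_back(cz[tc[a]] + tt * (cz[tc[b]] - cz[tc[a]]));
          };
          if (nin == 1 || nout == 1) {
            int lone = -1;
            for (int k = 0; k < 4; ++k)
              if ((nin == 1 && inside[k]) || (nout == 1 && !inside[k])) lone = k;
            int others[3], m = 0;
            for (int k = 0; k < 4; ++k) if (k != lone) others[m++] = k;
            emit(lone, others[0]); emit(lone, others[1]); emit(lone, others[2]);
          } else {  // 2 in / 2 out -> quad as two triangles
            int in_[2], out_[2], mi = 0, mo = 0;
            for (int k = 0; k < 4; ++k)
              if (inside[k]) in_[mi++] = k; else out_[mo++] = k;
            // quad vertices in cyclic order i0o0, i0o1, i1o1, i1o0
            emit(in_[0], out_[0]); emit(in_[0], out_[1]); emit(in_[1], out_[1]);
            emit(in_[0], out_[0]); emit(in_[1], out_[1]); emit(in_[1], out_[0]);
          }
        }
      }
  const R_xlen_t nv = vx.size();
  NumericMatrix verts(nv, 3);
  for (R_xlen_t i = 0; i < nv; ++i) {
    verts(i, 0) = vx[i]; verts(i, 1) = vy[i]; verts(i, 2) = vz[i];
  }
  IntegerMatrix tris(nv / 3, 3);
  for (R_xlen_t i = 0; i < nv / 3; ++i) {
    tris(i, 0) = (int)(3 * i + 1); tris(i, 1) = (int)(3 * i + 2);
    tris(i, 2) = (int)(3 * i + 3);
  }
  return List::create(_["vertices"] = verts, _["triangles"] = tris);
}

// Unique ordered pairs (label, neighbor label) over the 6-neighborhood,
// including 0 as a neighbor value. Used by segment post-processing and
// contact bookkeeping.
// [[Rcpp::export]]
IntegerMatrix cpp_label_adjacency(IntegerVector lab, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::set<std::pair<int, int>> pairs;
  auto at = [&](int x, int y, int z) -> int {
    return lab[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
  };
  const int D[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = at(x, y, z);
        for (int d = 0; d < 3; ++d) {
          int xx = x + D[d][0], yy = y + D[d][1], zz = z + D[d][2];
          if (xx >= nx || yy >= ny || zz >= nz) continue;
          int b = at(xx, yy, zz);
          if (a == b) continue;
          pairs.insert({a, b});
          pairs.insert({b, a});
        }
      }
  IntegerMatrix out(pairs.size(), 2);
  int i = 0;
  for (const auto &p : pairs) { out(i, 0) = p.first; out(i, 1) = p.second; ++i; }
  return out;
}
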