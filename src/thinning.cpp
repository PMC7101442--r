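// 3D binary-volume topology kernels: 26-connected component labelling,
// 26-neighbour counting, and Lee-style medial-axis thinning.
//
// Thinning deletes, in six directional subiterations per pass, border
// voxels that are "simple" for the (26, 6) connectivity pair: removing
// them changes neither the number of 26-connected object components nor
// the number of 6-connected background components locally. Simplicity is
// the standard local characterisation:
//   (a) the object voxels of the 3x3x3 neighbourhood minus the centre form
//       exactly one 26-connected component, and
//   (b) the background voxels of the 18-neighbourhood that are 6-adjacent
//       to the centre form exactly one 6-connected component within the
//       18-neighbourhood.
// End points (exactly one object neighbour) are never deleted, so branch
// tips survive; candidates are re-checked sequentially at deletion time so
// the parallel pass cannot break a 2-voxel-wide structure.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstring>
using namespace Rcpp;

static inline int lindex(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// ---- 27-cell neighbourhood machinery -------------------------------------

// nb[27]: object/background occupancy of the 3x3x3 neighbourhood,
// x fastest; centre is cell 13.
static void fill_neighborhood(const int *img, int x, int y, int z,
                              int nx, int ny, int nz, int nb[27]) {
  int c = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++c) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        nb[c] = (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz)
                  ? img[lindex(xx, yy, zz, nx, ny)] : 0;
      }
}

static inline void cell_dxyz(int c, int &dx, int &dy, int &dz) {
  dx = c % 3 - 1; dy = (c / 3) % 3 - 1; dz = c / 9 - 1;
}

// number of 26-connected components among object cells of nb, centre excluded
static int n_object_components26(const int nb[27]) {
  bool seen[27] = {false};
  int ncomp = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++ncomp;
    std::queue<int> q; q.push(s); seen[s] = true;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int cx, cy, cz; cell_dxyz(c, cx, cy, cz);
      for (int t = 0; t < 27; ++t) {
        if (t == 13 || seen[t] || !nb[t]) continue;
        int tx, ty, tz; cell_dxyz(t, tx, ty, tz);
        if (std::abs(tx - cx) <= 1 && std::abs(ty - cy) <= 1 && std::abs(tz - cz) <= 1) {
          seen[t] = true; q.push(t);
        }
      }
    }
  }
  return ncomp;
}

// number of 6-connected background components in the 18-neighbourhood that
// touch the centre by a face
static int n_background_components6(const int nb[27]) {
  bool in18[27], seen[27] = {false};
  for (int c = 0; c < 27; ++c) {
    int dx, dy, dz; cell_dxyz(c, dx, dy, dz);
    int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
    in18[c] = (c != 13) && manh <= 2 && !(std::abs(dx) == 1 && std::abs(dy) == 1 && std::abs(dz) == 1);
  }
  int ncomp = 0;
  for (int s = 0; s < 27; ++s) {
    int dx, dy, dz; cell_dxyz(s, dx, dy, dz);
    // seeds: background face-neighbours of the centre
    if (!in18[s] || nb[s] || seen[s]) continue;
    if (std::abs(dx) + std::abs(dy) + std::abs(dz) != 1) continue;
    ++ncomp;
    std::queue<int> q; q.push(s); seen[s] = true;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int cx, cy, cz; cell_dxyz(c, cx, cy, cz);
      for (int t = 0; t < 27; ++t) {
        if (!in18[t] || seen[t] || nb[t]) continue;
        int tx, ty, tz; cell_dxyz(t, tx, ty, tz);
        if (std::abs(tx - cx) + std::abs(ty - cy) + std::abs(tz - cz) == 1) {
          seen[t] = true; q.push(t);
        }
      }
    }
  }
  return ncomp;
}

static inline int neighbor_count(const int nb[27]) {
  int n = 0;
  for (int c = 0; c < 27; ++c) if (c != 13 && nb[c]) ++n;
  return n;
}

static bool is_simple(const int nb[27]) {
  return n_object_components26(nb) == 1 && n_background_components6(nb) == 1;
}

// ---- exported kernels ----------------------------------------------------

// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector img) {
  IntegerVector dims = img.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector lab(img.size());
  lab.attr("dim") = dims;
  const int *p = INTEGER(img);
  int *l = INTEGER(lab);
  std::memset(l, 0, sizeof(int) * img.size());
  int next = 0;
  std::vector<int> stack;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = lindex(x, y, z, nx, ny);
        if (!p[i] || l[i]) continue;
        ++next;
        stack.clear(); stack.push_back(i); l[i] = next;
        while (!stack.empty()) {
          int c = stack.back(); stack.pop_back();
          int cx = c % nx, cy = (c / nx) % ny, cz = c / (nx * ny);
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (!dx && !dy && !dz) continue;
                int xx = cx + dx, yy = cy + dy, zz = cz + dz;
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
                int t = lindex(xx, yy, zz, nx, ny);
                if (p[t] && !l[t]) { l[t] = next; stack.push_back(t); }
              }
        }
      }
  return lab;
}

// [[Rcpp::export]]
IntegerVector neighbor_count_cpp(IntegerVector img) {
  IntegerVector dims = img.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out(img.size());
  out.attr("dim") = dims;
  const int *p = INTEGER(img);
  int *o = INTEGER(out);
  int nb[27];
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = lindex(x, y, z, nx, ny);
        if (!p[i]) { o[i] = NA_INTEGER; continue; }
        fill_neighborhood(p, x, y, z, nx, ny, nz, nb);
        o[i] = neighbor_count(nb);
      }
  return out;
}

// [[Rcpp::export]]
IntegerVector thin_mask_cpp(IntegerVector img) {
  IntegerVector dims = img.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out = clone(img);
  out.attr("dim") = dims;
  int *p = INTEGER(out);
  const int dirs[6][3] = {{0, 0, -1}, {0, 0, 1}, {0, -1, 0}, {0, 1, 0},
                          {-1, 0, 0}, {1, 0, 0}};
  int nb[27];
  std::vector<int> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            int i = lindex(x, y, z, nx, ny);
            if (!p[i]) continue;
            int xx = x + dirs[d][0], yy = y + dirs[d][1], zz = z + dirs[d][2];
            int border = (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                          zz < 0 || zz >= nz) ? 1 : !p[lindex(xx, yy, zz, nx, ny)];
            if (!border) continue;
            fill_neighborhood(p, x, y, z, nx, ny, nz, nb);
            int nn = neighbor_count(nb);
            if (nn == 1) continue;           // end point: keep
            if (nn == 0) continue;           // isolated voxel: keep
            if (is_simple(nb)) cand.push_back(i);
          }
      // sequential re-check: neighbourhoods change as voxels are deleted
      for (size_t k = 0; k < cand.size(); ++k) {
        int i = cand[k];
        int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
        fill_neighborhood(p, x, y, z, nx, ny, nz, nb);
        int nn = neighbor_count(nb);
        if (nn <= 1) continue;
        if (is_simple(nb)) { p[i] = 0; changed = true; }
      }
    }
  }
  return out;
}
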