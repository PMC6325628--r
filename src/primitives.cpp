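#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Array layout: column-major, dim = (ny, nx, nz); linear index y + ny*(x + nx*z).

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Plane-wise separable correlation with a 1-D kernel applied along rows then
// columns of every z-slice. Border handling: replicate padding. The kernel
// origin follows the Matlab imfilter convention: element floor((N+1)/2)
// (1-based) sits on the output voxel, so even-sized kernels are supported.
// [[Rcpp::export]]
NumericVector conv_sep_cpp(NumericVector vol, IntegerVector dim, NumericVector kernel) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  const int nk = kernel.size();
  const int c = (nk + 1) / 2 - 1;            // 0-based origin index
  NumericVector out(vol.size());
  std::vector<double> tmp((size_t)ny * nx);

  for (int z = 0; z < nz; ++z) {
    const double *pz = REAL(vol) + (size_t)z * ny * nx;
    // pass 1: along y (rows within a column)
    for (int x = 0; x < nx; ++x) {
      const double *col = pz + (size_t)x * ny;
      double *tcol = tmp.data() + (size_t)x * ny;
      for (int y = 0; y < ny; ++y) {
        double s = 0.0;
        for (int k = 0; k < nk; ++k) {
          int yy = clampi(y + (k - c), 0, ny - 1);
          s += kernel[k] * col[yy];
        }
        tcol[y] = s;
      }
    }
    // pass 2: along x (across columns within a row)
    double *oz = REAL(out) + (size_t)z * ny * nx;
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        double s = 0.0;
        for (int k = 0; k < nk; ++k) {
          int xx = clampi(x + (k - c), 0, nx - 1);
          s += kernel[k] * tmp[(size_t)xx * ny + y];
        }
        oz[(size_t)x * ny + y] = s;
      }
    }
  }
  return out;
}

// Connected-component labelling of a 3-D logical mask, 6- or 26-connectivity.
// Labels are assigned in scan order (column-major), starting at 1.
// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  const size_t n = (size_t)ny * nx * nz;
  IntegerVector lab(n);
  std::vector<int> offy, offx, offz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        if (dy == 0 && dx == 0 && dz == 0) continue;
        int man = std::abs(dy) + std::abs(dx) + std::abs(dz);
        if (connectivity == 6 && man != 1) continue;
        offy.push_back(dy); offx.push_back(dx); offz.push_back(dz);
      }
  const int no = offy.size();
  int next = 0;
  std::vector<size_t> stack;
  for (size_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      size_t p = stack.back(); stack.pop_back();
      int z = p / ((size_t)ny * nx);
      int rem = p - (size_t)z * ny * nx;
      int x = rem / ny, y = rem % ny;
      for (int k = 0; k < no; ++k) {
        int yy = y + offy[k], xx = x + offx[k], zz = z + offz[k];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz) continue;
        size_t q = (size_t)yy + (size_t)ny * (xx + (size_t)nx * zz);
        if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  return lab;
}

// Number of 26-connected foreground neighbours of every voxel.
// [[Rcpp::export]]
IntegerVector neighbors26_cpp(LogicalVector mask, IntegerVector dim) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  IntegerVector out((size_t)ny * nx * nz);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        size_t p = (size_t)y + (size_t)ny * (x + (size_t)nx * z);
        if (!mask[p]) { out[p] = 0; continue; }
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dx = -1; dx <= 1; ++dx)
            for (int dy = -1; dy <= 1; ++dy) {
              if (!dy && !dx && !dz) continue;
              int yy = y + dy, xx = x + dx, zz = z + dz;
              if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz) continue;
              if (mask[(size_t)yy + (size_t)ny * (xx + (size_t)nx * zz)]) ++cnt;
            }
        out[p] = cnt;
      }
  return out;
}

// ---- simple-point machinery for 3-D thinning --------------------------------
// nb[27]: 3x3x3 neighbourhood in (dy, dx, dz) order, index = (dy+1) + 3*(dx+1) + 9*(dz+1).
// A voxel is simple iff exactly one 26-connected object component in N26 and
// exactly one 6-connected background component in N18 touching the centre
// 6-neighbourhood (Bertrand/Malandain characterisation).

static int object_components26(const bool nb[27]) {
  bool seen[27] = {false};
  int comp = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    ++comp;
    std::queue<int> q; q.push(i); seen[i] = true;
    while (!q.empty()) {
      int p = q.front(); q.pop();
      int py = p % 3, px = (p / 3) % 3, pz = p / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy) {
            int yy = py + dy, xx = px + dx, zz = pz + dz;
            if (yy < 0 || yy > 2 || xx < 0 || xx > 2 || zz < 0 || zz > 2) continue;
            int j = yy + 3 * xx + 9 * zz;
            if (j == 13 || j == p || seen[j] || !nb[j]) continue;
            seen[j] = true; q.push(j);
          }
    }
  }
  return comp;
}

static int background_components6(const bool nb[27]) {
  // 6-connected background components within the 18-neighbourhood (exclude
  // the 8 corners and the centre) that are 6-adjacent to the centre voxel.
  bool in18[27];
  for (int i = 0; i < 27; ++i) {
    int dy = i % 3 - 1, dx = (i / 3) % 3 - 1, dz = i / 9 - 1;
    int man = std::abs(dy) + std::abs(dx) + std::abs(dz);
    in18[i] = (man >= 1 && man <= 2);
  }
  bool seen[27] = {false};
  int comp = 0;
  for (int i = 0; i < 27; ++i) {
    int dy = i % 3 - 1, dx = (i / 3) % 3 - 1, dz = i / 9 - 1;
    if (std::abs(dy) + std::abs(dx) + std::abs(dz) != 1) continue;  // start from 6-neighbours
    if (nb[i] || seen[i]) continue;
    ++comp;
    std::queue<int> q; q.push(i); seen[i] = true;
    while (!q.empty()) {
      int p = q.front(); q.pop();
      int py = p % 3 - 1, px = (p / 3) % 3 - 1, pz = p / 9 - 1;
      const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int yy = py + d6[k][0], xx = px + d6[k][1], zz = pz + d6[k][2];
        if (yy < -1 || yy > 1 || xx < -1 || xx > 1 || zz < -1 || zz > 1) continue;
        int j = (yy + 1) + 3 * (xx + 1) + 9 * (zz + 1);
        if (j == 13 || !in18[j] || seen[j] || nb[j]) continue;
        seen[j] = true; q.push(j);
      }
    }
  }
  return comp;
}

// Medial-axis thinning of a 3-D mask by sequential removal of simple border
// points; voxels with at most one 26-neighbour (curve endpoints) are kept, so
// elongated objects reduce to their centreline. Deterministic scan order.
// [[Rcpp::export]]
LogicalVector thin3d_cpp(LogicalVector mask, IntegerVector dim) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  const size_t n = (size_t)ny * nx * nz;
  std::vector<char> m(n);
  for (size_t i = 0; i < n; ++i) m[i] = mask[i] ? 1 : 0;

  const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  bool nb[27];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      // collect candidates whose `dir` 6-neighbour is background
      std::vector<size_t> cand;
      for (int z = 0; z < nz; ++z)
        for (int x = 0; x < nx; ++x)
          for (int y = 0; y < ny; ++y) {
            size_t p = (size_t)y + (size_t)ny * (x + (size_t)nx * z);
            if (!m[p]) continue;
            int yy = y + d6[dir][0], xx = x + d6[dir][1], zz = z + d6[dir][2];
            bool bg = (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
                      ? true
                      : !m[(size_t)yy + (size_t)ny * (xx + (size_t)nx * zz)];
            if (bg) cand.push_back(p);
          }
      // sequential re-checked deletion preserves topology
      for (size_t ci = 0; ci < cand.size(); ++ci) {
        size_t p = cand[ci];
        if (!m[p]) continue;
        int z = p / ((size_t)ny * nx);
        int rem = p - (size_t)z * ny * nx;
        int x = rem / ny, y = rem % ny;
        int ncnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dx = -1; dx <= 1; ++dx)
            for (int dy = -1; dy <= 1; ++dy) {
              int idx = (dy + 1) + 3 * (dx + 1) + 9 * (dz + 1);
              if (idx == 13) { nb[idx] = true; continue; }
              int yy = y + dy, xx = x + dx, zz = z + dz;
              bool v = !(yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
                       && m[(size_t)yy + (size_t)ny * (xx + (size_t)nx * zz)];
              nb[idx] = v;
              if (v) ++ncnt;
            }
        if (ncnt <= 1) continue;                     // endpoint: keep
        if (object_components26(nb) != 1) continue;  // would split object
        if (background_components6(nb) != 1) continue;  // would create cavity/merge bg
        m[p] = 0;
        changed = true;
      }
    }
  }
  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = m[i] != 0;
  out.attr("dim") = dim;
  return out;
}
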