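// Texture-matrix construction kernels.
//
// All functions take a discretized region as a 3D integer array (passed as a
// flat IntegerVector plus dims, column-major as in R): voxels outside the
// region carry level 0, in-region voxels carry levels 1..Ng.  Feature
// formulas stay on the R side; only the counting loops live here.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// the 13 unique 3D directions (axis pairs up to sign)
static const int DIRS[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// [[Rcpp::export]]
IntegerVector cpp_glcm(IntegerVector levels, IntegerVector dim, int ng, int dist) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector out(ng * ng * 13);
  for (int d = 0; d < 13; ++d) {
    const int ox = DIRS[d][0] * dist, oy = DIRS[d][1] * dist, oz = DIRS[d][2] * dist;
    for (int z = 0; z < nz; ++z) {
      const int z2 = z + oz;
      if (z2 < 0 || z2 >= nz) continue;
      for (int y = 0; y < ny; ++y) {
        const int y2 = y + oy;
        if (y2 < 0 || y2 >= ny) continue;
        for (int x = 0; x < nx; ++x) {
          const int x2 = x + ox;
          if (x2 < 0 || x2 >= nx) continue;
          const int li = levels[idx3(x, y, z, nx, ny)];
          if (li == 0) continue;
          const int lj = levels[idx3(x2, y2, z2, nx, ny)];
          if (lj == 0) continue;
          // symmetric matrix
          out[(li - 1) + ng * (lj - 1) + ng * ng * d] += 1;
          out[(lj - 1) + ng * (li - 1) + ng * ng * d] += 1;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(ng, ng, 13);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_glrlm(IntegerVector levels, IntegerVector dim, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  int lmax = nx > ny ? nx : ny;
  if (nz > lmax) lmax = nz;
  IntegerVector out(ng * lmax * 13);
  for (int d = 0; d < 13; ++d) {
    const int ox = DIRS[d][0], oy = DIRS[d][1], oz = DIRS[d][2];
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) {
          const int lv = levels[idx3(x, y, z, nx, ny)];
          if (lv == 0) continue;
          // run start: predecessor out of bounds, outside region, or a
          // different level
          const int px = x - ox, py = y - oy, pz = z - oz;
          if (px >= 0 && px < nx && py >= 0 && py < ny && pz >= 0 && pz < nz &&
              levels[idx3(px, py, pz, nx, ny)] == lv)
            continue;
          int len = 1;
          int cx = x + ox, cy = y + oy, cz = z + oz;
          while (cx >= 0 && cx < nx && cy >= 0 && cy < ny && cz >= 0 && cz < nz &&
                 levels[idx3(cx, cy, cz, nx, ny)] == lv) {
            ++len; cx += ox; cy += oy; cz += oz;
          }
          out[(lv - 1) + ng * (len - 1) + ng * lmax * d] += 1;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(ng, lmax, 13);
  return out;
}

// 26-connected zones of equal gray level; returns a two-column matrix
// (level, zone size), one row per zone.
// [[Rcpp::export]]
IntegerMatrix cpp_glszm(IntegerVector levels, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zlev, zsize, stack;
  for (int start = 0; start < n; ++start) {
    if (seen[start] || levels[start] == 0) continue;
    const int lv = levels[start];
    int size = 0;
    stack.clear();
    stack.push_back(start);
    seen[start] = 1;
    while (!stack.empty()) {
      const int v = stack.back(); stack.pop_back();
      ++size;
      const int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz) {
        const int z2 = z + dz;
        if (z2 < 0 || z2 >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int y2 = y + dy;
          if (y2 < 0 || y2 >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            const int x2 = x + dx;
            if (x2 < 0 || x2 >= nx) continue;
            const int w = idx3(x2, y2, z2, nx, ny);
            if (!seen[w] && levels[w] == lv) {
              seen[w] = 1;
              stack.push_back(w);
            }
          }
        }
      }
    }
    zlev.push_back(lv);
    zsize.push_back(size);
  }
  IntegerMatrix out(zlev.size(), 2);
  for (size_t i = 0; i < zlev.size(); ++i) {
    out(i, 0) = zlev[i];
    out(i, 1) = zsize[i];
  }
  return out;
}

// NGTDM accumulators: per level i, s_i = sum over region voxels of level i
// (with at least one valid neighbour) of |i - mean(valid neighbours)|, and
// n_i = count of such voxels.  Neighbourhood = Chebyshev radius `dist`,
// centre excluded.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector levels, IntegerVector dim, int ng, int dist) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng, 2); // col 0: s_i, col 1: n_i
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        const int lv = levels[idx3(x, y, z, nx, ny)];
        if (lv == 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dz = -dist; dz <= dist; ++dz) {
          const int z2 = z + dz;
          if (z2 < 0 || z2 >= nz) continue;
          for (int dy = -dist; dy <= dist; ++dy) {
            const int y2 = y + dy;
            if (y2 < 0 || y2 >= ny) continue;
            for (int dx = -dist; dx <= dist; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              const int x2 = x + dx;
              if (x2 < 0 || x2 >= nx) continue;
              const int lw = levels[idx3(x2, y2, z2, nx, ny)];
              if (lw > 0) { sum += lw; ++cnt; }
            }
          }
        }
        if (cnt > 0) {
          out(lv - 1, 0) += std::fabs(lv - sum / cnt);
          out(lv - 1, 1) += 1.0;
        }
      }
    }
  }
  return out;
}

// Dependence matrix: P(i, d+1) counts region voxels of level i with d
// neighbours (Chebyshev radius `dist`, centre excluded) whose level differs
// by at most `alpha`.
// [[Rcpp::export]]
IntegerMatrix cpp_gldm(IntegerVector levels, IntegerVector dim, int ng, int dist, int alpha) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int w = 2 * dist + 1;
  const int ndmax = w * w * w - 1;
  IntegerMatrix out(ng, ndmax + 1);
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        const int lv = levels[idx3(x, y, z, nx, ny)];
        if (lv == 0) continue;
        int dep = 0;
        for (int dz = -dist; dz <= dist; ++dz) {
          const int z2 = z + dz;
          if (z2 < 0 || z2 >= nz) continue;
          for (int dy = -dist; dy <= dist; ++dy) {
            const int y2 = y + dy;
            if (y2 < 0 || y2 >= ny) continue;
            for (int dx = -dist; dx <= dist; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              const int x2 = x + dx;
              if (x2 < 0 || x2 >= nx) continue;
              const int lw = levels[idx3(x2, y2, z2, nx, ny)];
              if (lw > 0 && std::abs(lw - lv) <= alpha) ++dep;
            }
          }
        }
        out(lv - 1, dep) += 1;
      }
    }
  }
  return out;
}

// Number of 26-connected foreground components of a binary array.
// [[Rcpp::export]]
int cpp_n_components26(IntegerVector mask, IntegerVector dim) {
  IntegerMatrix zones = cpp_glszm(mask, dim);
  return zones.nrow();
}
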