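#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// 3D watershed of the intensity landscape restricted to its positive support.
//
// The volume is flooded basin-by-basin starting from its regional maxima
// (equivalently: watershed of the negated image), visiting voxels in order of
// decreasing intensity. Zero/negative voxels are background and are never
// flooded. A voxel reachable from two distinct basins becomes a watershed
// line and keeps label 0. 6-connectivity (face neighbors) throughout.
//
// Determinism: regional maxima are discovered by scanning voxels in
// lexicographic (z, y, x) order, a flat maximum (plateau) forms a single
// marker, and intensity ties in the flooding queue are broken
// first-in-first-out.
//
// The array is stored column-major with dim = (nz, ny, nx), so linear index
// i = z + nz * (y + ny * x). Lexicographic (z, y, x) order is achieved by
// looping z (outer), then y, then x (inner).

namespace {

struct QEntry {
  double v;
  uint64_t seq;
  int idx;
};

struct QCompare {
  bool operator()(const QEntry& a, const QEntry& b) const {
    if (a.v != b.v) return a.v < b.v;  // max-heap on intensity
    return a.seq > b.seq;              // FIFO among equal intensities
  }
};

}  // namespace

// [[Rcpp::export(name = ".cpp_watershed")]]
IntegerVector cpp_watershed(NumericVector vol, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  const double* v = REAL(vol);

  IntegerVector labels_out(n);
  int* lab = INTEGER(labels_out);
  std::vector<uint8_t> state(n, 0);  // 0 untouched, 1 queued, 2 done

  // neighbor offsets in linear index space (validity checked per-axis)
  const int dz[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, -1, 1};

  auto lin = [&](int z, int y, int x) -> R_xlen_t {
    return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * x);
  };

  // ---- Phase 1: regional maxima of the positive support (plateau-aware) ---
  std::vector<uint8_t> seen(n, 0);
  std::vector<int> comp, bfs;
  int n_labels = 0;
  std::vector<int> seeds;  // all voxels of all maxima plateaus, in order

  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = lin(z, y, x);
        if (seen[i] || v[i] <= 0) continue;
        // BFS over the equal-valued connected plateau containing i
        const double val = v[i];
        bool is_max = true;
        comp.clear();
        bfs.clear();
        bfs.push_back((int)i);
        seen[i] = 1;
        while (!bfs.empty()) {
          int cur = bfs.back();
          bfs.pop_back();
          comp.push_back(cur);
          int cz = cur % nz, rem = cur / nz;
          int cy = rem % ny, cx = rem / ny;
          for (int k = 0; k < 6; ++k) {
            int zz = cz + dz[k], yy = cy + dy[k], xx = cx + dx[k];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            R_xlen_t j = lin(zz, yy, xx);
            if (v[j] > val) {
              is_max = false;
            } else if (v[j] == val && !seen[j]) {
              seen[j] = 1;
              bfs.push_back((int)j);
            }
          }
        }
        if (is_max) {
          ++n_labels;
          for (size_t k = 0; k < comp.size(); ++k) {
            lab[comp[k]] = n_labels;
            seeds.push_back(comp[k]);
          }
        }
      }
    }
  }

  // ---- Phase 2: priority flood from the maxima downhill ----
  std::priority_queue<QEntry, std::vector<QEntry>, QCompare> pq;
  uint64_t seq = 0;
  for (size_t k = 0; k < seeds.size(); ++k) {
    int i = seeds[k];
    state[i] = 1;
    pq.push(QEntry{v[i], seq++, i});
  }

  while (!pq.empty()) {
    QEntry e = pq.top();
    pq.pop();
    int i = e.idx;
    if (state[i] == 2) continue;

    int cz = i % nz, rem = i / nz;
    int cy = rem % ny, cx = rem / ny;

    if (lab[i] == 0) {
      // decide label from already-settled neighbors
      int found = 0;  // 0 none, -1 conflict, >0 unique label
      for (int k = 0; k < 6; ++k) {
        int zz = cz + dz[k], yy = cy + dy[k], xx = cx + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t j = lin(zz, yy, xx);
        if (state[j] == 2 && lab[j] > 0) {
          if (found == 0)
            found = lab[j];
          else if (found != lab[j])
            found = -1;
        }
      }
      lab[i] = (found > 0) ? found : 0;  // conflict or orphan -> boundary
    }
    state[i] = 2;

    for (int k = 0; k < 6; ++k) {
      int zz = cz + dz[k], yy = cy + dy[k], xx = cx + dx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      R_xlen_t j = lin(zz, yy, xx);
      if (state[j] == 0 && v[j] > 0) {
        state[j] = 1;
        pq.push(QEntry{v[j], seq++, (int)j});
      }
    }
  }

  labels_out.attr("n_labels") = n_labels;
  return labels_out;
}
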