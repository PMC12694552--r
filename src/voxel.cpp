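// Voxel-level primitives for the segmentation and morphometry stages.
// Volumes are 3D arrays with dim = (nz, ny, nx), R column-major, so the
// linear index is z + nz*(y + ny*x); scan order "(z, y, x) lexicographic"
// therefore iterates z in the outermost loop.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline R_xlen_t lin(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

// neighbour offsets in deterministic (dz, dy, dx) ascending order
static std::vector<std::array<int,3> > offsets(int connectivity) {
  std::vector<std::array<int,3> > off;
  if (connectivity == 6) {
    int d6[6][3] = {{-1,0,0},{0,-1,0},{0,0,-1},{0,0,1},{0,1,0},{1,0,0}};
    for (int i = 0; i < 6; ++i) off.push_back({d6[i][0], d6[i][1], d6[i][2]});
  } else {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          if (dz || dy || dx) off.push_back({dz, dy, dx});
  }
  return off;
}

// [[Rcpp::export(name = ".cpp_region_grow")]]
IntegerVector cpp_region_grow(NumericVector vol, LogicalVector barrier,
                              IntegerVector dim, double tol,
                              int connectivity, int min_region_vox) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = vol.size();
  IntegerVector labels(n, 0);
  std::vector<std::array<int,3> > off = offsets(connectivity);
  std::vector<double> rsum;   rsum.push_back(0.0);   // index 0 unused
  std::vector<double> rcount; rcount.push_back(0.0);

  // stage 1: deterministic seeded flood with running-mean criterion
  std::queue<R_xlen_t> q;
  int next_id = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = lin(z, y, x, nz, ny);
        if (labels[i] != 0 || barrier[i]) continue;
        ++next_id;
        rsum.push_back(vol[i]);
        rcount.push_back(1.0);
        labels[i] = next_id;
        q.push(i);
        while (!q.empty()) {
          R_xlen_t c = q.front(); q.pop();
          int cx = (int)(c / ((R_xlen_t)nz * ny));
          int cy = (int)((c / nz) % ny);
          int cz = (int)(c % nz);
          for (size_t k = 0; k < off.size(); ++k) {
            int zz = cz + off[k][0], yy = cy + off[k][1], xx = cx + off[k][2];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
            R_xlen_t j = lin(zz, yy, xx, nz, ny);
            if (labels[j] != 0 || barrier[j]) continue;
            double mean = rsum[next_id] / rcount[next_id];
            if (std::fabs(vol[j] - mean) <= tol) {
              labels[j] = next_id;
              rsum[next_id] += vol[j];
              rcount[next_id] += 1.0;
              q.push(j);
            }
          }
        }
      }
  if (next_id == 0) stop("no seed voxels: input is entirely barrier");

  // stage 2: absorb remaining (barrier) voxels into the adjacent region with
  // nearest mean intensity; repeated passes handle barrier-only neighbourhoods
  bool pending = true;
  while (pending) {
    pending = false;
    bool changed = false;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          R_xlen_t i = lin(z, y, x, nz, ny);
          if (labels[i] != 0) continue;
          int best = 0; double bestd = 0.0;
          for (size_t k = 0; k < off.size(); ++k) {
            int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
            R_xlen_t j = lin(zz, yy, xx, nz, ny);
            int lj = labels[j];
            if (lj == 0) continue;
            double d = std::fabs(vol[i] - rsum[lj] / rcount[lj]);
            if (best == 0 || d < bestd || (d == bestd && lj < best)) { best = lj; bestd = d; }
          }
          if (best != 0) {
            labels[i] = best;
            rsum[best] += vol[i];
            rcount[best] += 1.0;
            changed = true;
          } else pending = true;
        }
    if (pending && !changed) stop("internal error: unassigned voxels with no labelled neighbour");
  }

  // stage 3: merge sub-threshold fragments into adjacent region of nearest mean
  if (min_region_vox > 1 && next_id > 1) {
    std::vector<std::vector<R_xlen_t> > members(next_id + 1);
    for (R_xlen_t i = 0; i < n; ++i) members[labels[i]].push_back(i);
    for (;;) {
      int victim = 0; double vcount = 0.0;
      for (int r = 1; r <= next_id; ++r)
        if (rcount[r] > 0 && rcount[r] < min_region_vox)
          if (victim == 0 || rcount[r] < vcount) { victim = r; vcount = rcount[r]; }
      if (victim == 0) break;
      double vmean = rsum[victim] / rcount[victim];
      int best = 0; double bestd = 0.0;
      for (size_t m = 0; m < members[victim].size(); ++m) {
        R_xlen_t c = members[victim][m];
        int cx = (int)(c / ((R_xlen_t)nz * ny));
        int cy = (int)((c / nz) % ny);
        int cz = (int)(c % nz);
        for (size_t k = 0; k < off.size(); ++k) {
          int zz = cz + off[k][0], yy = cy + off[k][1], xx = cx + off[k][2];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          int lj = labels[lin(zz, yy, xx, nz, ny)];
          if (lj == 0 || lj == victim) continue;
          double d = std::fabs(vmean - rsum[lj] / rcount[lj]);
          if (best == 0 || d < bestd || (d == bestd && lj < best)) { best = lj; bestd = d; }
        }
      }
      if (best == 0) break;  // no neighbour (single region left)
      for (size_t m = 0; m < members[victim].size(); ++m) labels[members[victim][m]] = best;
      members[best].insert(members[best].end(), members[victim].begin(), members[victim].end());
      members[victim].clear();
      rsum[best] += rsum[victim]; rcount[best] += rcount[victim];
      rsum[victim] = 0.0; rcount[victim] = 0.0;
    }
  }

  // relabel compactly by first occurrence in (z, y, x) scan order
  std::vector<int> remap(next_id + 1, 0);
  int out_id = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int l = labels[lin(z, y, x, nz, ny)];
        if (remap[l] == 0) remap[l] = ++out_id;
      }
  for (R_xlen_t i = 0; i < n; ++i) labels[i] = remap[labels[i]];
  labels.attr("dim") = dim;
  return labels;
}

// separable Gaussian blur with replicate padding; sigma <= 0 skips an axis
// [[Rcpp::export(name = ".cpp_gaussian_blur3d")]]
NumericVector cpp_gaussian_blur3d(NumericVector vol, IntegerVector dim,
                                  double sz, double sy, double sx) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector cur = clone(vol);
  double sig[3] = {sz, sy, sx};
  for (int axis = 0; axis < 3; ++axis) {
    double s = sig[axis];
    if (s <= 0) continue;
    int rad = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> w(2 * rad + 1);
    double tot = 0;
    for (int k = -rad; k <= rad; ++k) { w[k + rad] = std::exp(-0.5 * k * k / (s * s)); tot += w[k + rad]; }
    for (size_t k = 0; k < w.size(); ++k) w[k] /= tot;
    NumericVector nxt(cur.size());
    int nax[3] = {nz, ny, nx};
    int nA = nax[axis];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          double acc = 0;
          int p[3] = {z, y, x};
          for (int k = -rad; k <= rad; ++k) {
            int q = p[axis] + k;
            if (q < 0) q = 0; else if (q >= nA) q = nA - 1;
            int zz = (axis == 0) ? q : z, yy = (axis == 1) ? q : y, xx = (axis == 2) ? q : x;
            acc += w[k + rad] * cur[lin(zz, yy, xx, nz, ny)];
          }
          nxt[lin(z, y, x, nz, ny)] = acc;
        }
    cur = nxt;
  }
  cur.attr("dim") = dim;
  return cur;
}

// hysteresis: keep weak pixels 8-connected to a strong pixel (2D matrix, col-major)
// [[Rcpp::export(name = ".cpp_hysteresis2d")]]
LogicalVector cpp_hysteresis2d(LogicalVector weak, LogicalVector strong,
                               int nrow, int ncol) {
  LogicalVector keep(weak.size(), FALSE);
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < strong.size(); ++i)
    if (strong[i]) { keep[i] = TRUE; q.push(i); }
  while (!q.empty()) {
    R_xlen_t c = q.front(); q.pop();
    int r = (int)(c % nrow), k = (int)(c / nrow);
    for (int dr = -1; dr <= 1; ++dr)
      for (int dk = -1; dk <= 1; ++dk) {
        if (!dr && !dk) continue;
        int rr = r + dr, kk = k + dk;
        if (rr < 0 || rr >= nrow || kk < 0 || kk >= ncol) continue;
        R_xlen_t j = (R_xlen_t)rr + (R_xlen_t)nrow * kk;
        if (weak[j] && !keep[j]) { keep[j] = TRUE; q.push(j); }
      }
  }
  return keep;
}

// 1D squared distance transform, Felzenszwalb & Huttenlocher lower envelope
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> zed(n + 1);
  int k = 0;
  v[0] = 0; zed[0] = -std::numeric_limits<double>::infinity();
  zed[1] = std::numeric_limits<double>::infinity();
  for (int qi = 1; qi < n; ++qi) {
    double s;
    for (;;) {
      s = ((f[qi] + qi * qi) - (f[v[k]] + v[k] * v[k])) / (2.0 * qi - 2.0 * v[k]);
      if (s <= zed[k]) { --k; } else break;
    }
    ++k; v[k] = qi; zed[k] = s; zed[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int qi = 0; qi < n; ++qi) {
    while (zed[k + 1] < qi) ++k;
    double dq = qi - v[k];
    d[qi] = dq * dq + f[v[k]];
  }
}

// squared Euclidean distance (in voxels) from each true voxel to the nearest
// false voxel; array boundaries are not treated as background
// [[Rcpp::export(name = ".cpp_edt3d_sq")]]
NumericVector cpp_edt3d_sq(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double INF = 1e20;
  NumericVector d(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) d[i] = mask[i] ? INF : 0.0;
  std::vector<double> f(std::max(nz, std::max(ny, nx))), g(f.size());
  // z, then y, then x
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) f[z] = d[lin(z, y, x, nz, ny)];
      dt1d(f, g, nz);
      for (int z = 0; z < nz; ++z) d[lin(z, y, x, nz, ny)] = g[z];
    }
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) f[y] = d[lin(z, y, x, nz, ny)];
      dt1d(f, g, ny);
      for (int y = 0; y < ny; ++y) d[lin(z, y, x, nz, ny)] = g[y];
    }
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = d[lin(z, y, x, nz, ny)];
      dt1d(f, g, nx);
      for (int x = 0; x < nx; ++x) d[lin(z, y, x, nz, ny)] = g[x];
    }
  d.attr("dim") = dim;
  return d;
}

// 26-neighbourhood local maxima of a non-negative field, restricted to field > 0
// [[Rcpp::export(name = ".cpp_local_maxima3d")]]
LogicalVector cpp_local_maxima3d(NumericVector field, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  LogicalVector out(field.size(), FALSE);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = lin(z, y, x, nz, ny);
        double v = field[i];
        if (v <= 0) continue;
        bool ismax = true;
        for (int dz = -1; dz <= 1 && ismax; ++dz)
          for (int dy = -1; dy <= 1 && ismax; ++dy)
            for (int dx = -1; dx <= 1 && ismax; ++dx) {
              if (!dz && !dy && !dx) continue;
              int zz = z + dz, yy = y + dy, xx = x + dx;
              if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
              if (field[lin(zz, yy, xx, nz, ny)] > v) ismax = false;
            }
        if (ismax) out[i] = TRUE;
      }
  out.attr("dim") = dim;
  return out;
}
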