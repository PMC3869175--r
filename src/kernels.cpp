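// Low-level volumetric kernels shared by the registration, shape-analysis and
// metric modules. All grids are dense double arrays in R's column-major
// layout, dims (nx, ny, nz); point coordinates are 0-based voxel indices.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <queue>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Trilinear interpolation of a scalar volume at arbitrary points.
// Coordinates outside the grid are clamped to the boundary (constant
// extrapolation), which is the behaviour the registration band model needs.
// [[Rcpp::export(name = ".c_trilerp")]]
NumericVector c_trilerp(NumericVector vol, IntegerVector dims,
                        NumericMatrix pts) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = pts.nrow();
  NumericVector out(n);
  const double* v = REAL(vol);
  for (int p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
    if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
    if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 > nx - 2) x0 = nx - 2 < 0 ? 0 : nx - 2;
    if (y0 > ny - 2) y0 = ny - 2 < 0 ? 0 : ny - 2;
    if (z0 > nz - 2) z0 = nz - 2 < 0 ? 0 : nz - 2;
    int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
        z1 = std::min(z0 + 1, nz - 1);
    double fx = x - x0, fy = y - y0, fz = z - z0;
    #define V(i,j,k) v[(i) + nx * ((j) + (size_t)ny * (k))]
    double c00 = V(x0,y0,z0) * (1-fx) + V(x1,y0,z0) * fx;
    double c10 = V(x0,y1,z0) * (1-fx) + V(x1,y1,z0) * fx;
    double c01 = V(x0,y0,z1) * (1-fx) + V(x1,y0,z1) * fx;
    double c11 = V(x0,y1,z1) * (1-fx) + V(x1,y1,z1) * fx;
    #undef V
    double c0 = c00 * (1-fy) + c10 * fy;
    double c1 = c01 * (1-fy) + c11 * fy;
    out[p] = c0 * (1-fz) + c1 * fz;
  }
  return out;
}

// Adjoint of c_trilerp: accumulate point values onto the grid with the same
// trilinear weights (used for control-grid gradients). Out-of-range points
// accumulate onto the clamped boundary cell.
// [[Rcpp::export(name = ".c_triscatter")]]
NumericVector c_triscatter(IntegerVector dims, NumericMatrix pts,
                           NumericVector vals) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((size_t)nx * ny * nz);
  double* o = REAL(out);
  const int n = pts.nrow();
  for (int p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
    if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
    if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 > nx - 2) x0 = nx - 2 < 0 ? 0 : nx - 2;
    if (y0 > ny - 2) y0 = ny - 2 < 0 ? 0 : ny - 2;
    if (z0 > nz - 2) z0 = nz - 2 < 0 ? 0 : nz - 2;
    int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
        z1 = std::min(z0 + 1, nz - 1);
    double fx = x - x0, fy = y - y0, fz = z - z0;
    double val = vals[p];
    #define A(i,j,k,w) o[(i) + nx * ((j) + (size_t)ny * (k))] += val * (w)
    A(x0,y0,z0, (1-fx)*(1-fy)*(1-fz));
    A(x1,y0,z0, fx*(1-fy)*(1-fz));
    A(x0,y1,z0, (1-fx)*fy*(1-fz));
    A(x1,y1,z0, fx*fy*(1-fz));
    A(x0,y0,z1, (1-fx)*(1-fy)*fz);
    A(x1,y0,z1, fx*(1-fy)*fz);
    A(x0,y1,z1, (1-fx)*fy*fz);
    A(x1,y1,z1, fx*fy*fz);
    #undef A
  }
  return out;
}

// 1-D squared distance transform (Felzenszwalb & Huttenlocher lower
// envelope), run separably along the three axes. `f` holds 0 on sites and
// +inf elsewhere on entry; anisotropic spacing is handled by the caller via
// pre/post scaling per axis, so here spacing is passed per axis.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& vtx, std::vector<double>& zz,
                 int n, double step) {
  int k = 0;
  vtx[0] = 0;
  zz[0] = -INFINITY; zz[1] = INFINITY;
  const double s2 = step * step;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = vtx[k];
      s = ((f[q] + s2*q*q) - (f[p] + s2*p*p)) / (2.0*s2*q - 2.0*s2*p);
      if (s <= zz[k]) { --k; } else break;
    }
    ++k;
    vtx[k] = q;
    zz[k] = s; zz[k+1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zz[k+1] < (double)q) ++k;
    int p = vtx[k];
    d[q] = s2 * (q - p) * (q - p) + f[p];
  }
}

// Squared Euclidean distance transform (mm^2) to the foreground set.
// mask != 0 marks sites (distance 0 there).
// [[Rcpp::export(name = ".c_edt_sq")]]
NumericVector c_edt_sq(LogicalVector mask, IntegerVector dims,
                       NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t N = (size_t)nx * ny * nz;
  NumericVector out(N);
  double* d = REAL(out);
  const double INF = 1e30;
  for (size_t i = 0; i < N; ++i) d[i] = mask[i] ? 0.0 : INF;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), dd(nmax), zz(nmax + 1);
  std::vector<int> vtx(nmax);
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t base = nx * ((size_t)j + (size_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = d[base + i];
      dt1d(f, dd, vtx, zz, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) d[base + i] = dd[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)i + (size_t)nx * ny * (size_t)k;
      for (int j = 0; j < ny; ++j) f[j] = d[base + (size_t)nx * j];
      dt1d(f, dd, vtx, zz, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) d[base + (size_t)nx * j] = dd[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)i + (size_t)nx * j;
      for (int k = 0; k < nz; ++k) f[k] = d[base + (size_t)nx * ny * k];
      dt1d(f, dd, vtx, zz, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) d[base + (size_t)nx * ny * k] = dd[k];
    }
  return out;
}

// 6-connected component labelling; returns integer labels (0 = background),
// components numbered in decreasing voxel-count order starting at 1.
// [[Rcpp::export(name = ".c_label6")]]
IntegerVector c_label6(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t N = (size_t)nx * ny * nz;
  IntegerVector lab(N);
  int next = 0;
  std::vector<size_t> stack;
  std::vector<size_t> counts;
  for (size_t s = 0; s < N; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    size_t cnt = 0;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      size_t cur = stack.back(); stack.pop_back();
      ++cnt;
      int i = (int)(cur % nx);
      int j = (int)((cur / nx) % ny);
      int k = (int)(cur / ((size_t)nx * ny));
      const int di[6] = {-1,1,0,0,0,0};
      const int dj[6] = {0,0,-1,1,0,0};
      const int dk[6] = {0,0,0,0,-1,1};
      for (int t = 0; t < 6; ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        size_t nb = (size_t)ii + nx * ((size_t)jj + (size_t)ny * kk);
        if (mask[nb] && !lab[nb]) { lab[nb] = next; stack.push_back(nb); }
      }
    }
    counts.push_back(cnt);
  }
  // relabel by decreasing size
  std::vector<int> order(next);
  for (int i = 0; i < next; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return counts[a] > counts[b]; });
  std::vector<int> remap(next + 1, 0);
  for (int r = 0; r < next; ++r) remap[order[r] + 1] = r + 1;
  for (size_t s = 0; s < N; ++s) if (lab[s]) lab[s] = remap[lab[s]];
  return lab;
}

// Voxelize a closed triangulated surface by vertical (+z) ray parity.
// verts: nv x 3 in 0-based voxel coordinates; tris: nt x 3 (0-based vertex
// ids). A voxel (i,j,k) is foreground when the column ray through its centre
// crosses the surface an odd number of times below/above per the parity
// fill between sorted crossing pairs. Degenerate triangles are skipped.
// [[Rcpp::export(name = ".c_voxelize_parity")]]
LogicalVector c_voxelize_parity(NumericMatrix verts, IntegerMatrix tris,
                                IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((size_t)nx * ny * nz);
  const int nt = tris.nrow();
  // bin triangles by integer (i, j) columns they may cover
  std::vector<std::vector<int>> bins((size_t)nx * ny);
  for (int t = 0; t < nt; ++t) {
    double x0 = verts(tris(t,0),0), x1 = verts(tris(t,1),0), x2 = verts(tris(t,2),0);
    double y0 = verts(tris(t,0),1), y1 = verts(tris(t,1),1), y2 = verts(tris(t,2),1);
    int ilo = clampi((int)std::floor(std::min(x0, std::min(x1, x2))), 0, nx-1);
    int ihi = clampi((int)std::ceil (std::max(x0, std::max(x1, x2))), 0, nx-1);
    int jlo = clampi((int)std::floor(std::min(y0, std::min(y1, y2))), 0, ny-1);
    int jhi = clampi((int)std::ceil (std::max(y0, std::max(y1, y2))), 0, ny-1);
    for (int j = jlo; j <= jhi; ++j)
      for (int i = ilo; i <= ihi; ++i)
        bins[(size_t)i + (size_t)nx * j].push_back(t);
  }
  std::vector<double> cross;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      const std::vector<int>& tl = bins[(size_t)i + (size_t)nx * j];
      if (tl.empty()) continue;
      cross.clear();
      // tiny fixed in-plane offset avoids rays hitting shared edges exactly
      const double px = i + 1.23e-4, py = j + 4.57e-4;
      for (int idx : tl) {
        int t = idx;
        double ax = verts(tris(t,0),0), ay = verts(tris(t,0),1), az = verts(tris(t,0),2);
        double bx = verts(tris(t,1),0), by = verts(tris(t,1),1), bz = verts(tris(t,1),2);
        double cx = verts(tris(t,2),0), cy = verts(tris(t,2),1), cz = verts(tris(t,2),2);
        // 2-D barycentric in the xy projection
        double d00x = bx-ax, d00y = by-ay, d01x = cx-ax, d01y = cy-ay;
        double det = d00x*d01y - d00y*d01x;
        if (std::fabs(det) < 1e-14) continue; // degenerate in projection
        double qx = px-ax, qy = py-ay;
        double u = (qx*d01y - qy*d01x) / det;
        double v = (d00x*qy - d00y*qx) / det;
        if (u < 0 || v < 0 || u + v > 1) continue;
        double z = az + u*(bz-az) + v*(cz-az);
        cross.push_back(z);
      }
      if (cross.size() < 2) continue;
      std::sort(cross.begin(), cross.end());
      // dedupe near-identical crossings (shared edges / vertices)
      std::vector<double> cc;
      for (double z : cross) {
        if (cc.empty() || z - cc.back() > 1e-9) cc.push_back(z);
        else cc.back() = 0.5 * (cc.back() + z); // merge
      }
      for (size_t p = 0; p + 1 < cc.size(); p += 2) {
        int klo = (int)std::ceil(cc[p]);
        int khi = (int)std::floor(cc[p+1]);
        klo = clampi(klo, 0, nz-1);
        khi = clampi(khi, -1, nz-1);
        for (int k = klo; k <= khi; ++k)
          out[(size_t)i + nx * ((size_t)j + (size_t)ny * k)] = true;
      }
    }
  return out;
}

// For each query point, index (1-based) of the nearest reference point and
// the squared distance. Brute force with early-exit pruning on running best.
// [[Rcpp::export(name = ".c_nn_bruteforce")]]
List c_nn_bruteforce(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  IntegerVector idx(nq);
  NumericVector d2(nq);
  for (int q = 0; q < nq; ++q) {
    double best = INFINITY; int bi = 0;
    double qx = query(q,0), qy = query(q,1), qz = query(q,2);
    for (int r = 0; r < nr; ++r) {
      double dx = ref(r,0) - qx;
      double dd = dx * dx;
      if (dd >= best) continue;
      double dy = ref(r,1) - qy; dd += dy * dy;
      if (dd >= best) continue;
      double dz = ref(r,2) - qz; dd += dz * dz;
      if (dd < best) { best = dd; bi = r; }
    }
    idx[q] = bi + 1;
    d2[q] = best;
  }
  return List::create(_["idx"] = idx, _["d2"] = d2);
}
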