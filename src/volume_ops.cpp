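// Low-level 3D grid primitives used across the package: separable Gaussian
// smoothing, anisotropic Euclidean distance transform, connected-component
// labelling, multi-source geodesic region growing, local surface-area weights
// and spatiotemporal local maxima. All arrays are column-major (x fastest),
// matching R's array layout; voxel sizes are physical (micrometres).
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double BIG = 1e20;

// ---------------------------------------------------------------------------
// separable Gaussian blur, reflecting boundaries; sigma per axis in voxels
// ---------------------------------------------------------------------------
static void blur_axis(std::vector<double> &v, int nx, int ny, int nz,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; i++) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &w : k) w /= s;

  int n = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  long stride = (axis == 0) ? 1L : (axis == 1) ? (long)nx : (long)nx * ny;
  std::vector<double> line(n);

  // iterate over all lines along `axis`
  int d1 = (axis == 0) ? ny : nx;
  int d2 = (axis == 2) ? ny : nz;
  for (int b = 0; b < d2; b++) {
    for (int a = 0; a < d1; a++) {
      long base;
      if (axis == 0)      base = (long)nx * (a + (long)ny * b);
      else if (axis == 1) base = a + (long)nx * ny * b;
      else                base = a + (long)nx * b;
      for (int i = 0; i < n; i++) line[i] = v[base + stride * i];
      for (int i = 0; i < n; i++) {
        double acc = 0;
        for (int j = -r; j <= r; j++) {
          int p = i + j;
          if (p < 0) p = -p - 1;            // reflect
          if (p >= n) p = 2 * n - p - 1;
          if (p < 0) p = 0;
          if (p >= n) p = n - 1;
          acc += k[j + r] * line[p];
        }
        v[base + stride * i] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_blur3d(NumericVector vol, IntegerVector dim,
                               NumericVector sigma_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> v(vol.begin(), vol.end());
  for (int a = 0; a < 3; a++) blur_axis(v, nx, ny, nz, a, sigma_vox[a]);
  NumericVector out(v.begin(), v.end());
  return out;
}

// ---------------------------------------------------------------------------
// anisotropic squared EDT (Felzenszwalb & Huttenlocher lower envelope)
// ---------------------------------------------------------------------------
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 int n, double s) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;   // true infinities: f is capped at BIG, so sA stays finite
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    double xq = q * s, sA;
    while (true) {
      double xv = v[k] * s;
      sA = (f[q] + xq * xq - (f[v[k]] + xv * xv)) / (2 * (xq - xv));
      if (sA <= z[k]) {
        k--;
      } else break;
    }
    k++;
    v[k] = q;
    z[k] = sA;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double x = q * s;
    while (z[k + 1] < x) k++;
    double dx = x - v[k] * s;
    d[q] = dx * dx + f[v[k]];
  }
}

static void edt_axis(std::vector<double> &sq, int nx, int ny, int nz,
                     int axis, double s) {
  int n = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  long stride = (axis == 0) ? 1L : (axis == 1) ? (long)nx : (long)nx * ny;
  std::vector<double> f(n), d(n), z(n + 1);
  std::vector<int> v(n);
  int d1 = (axis == 0) ? ny : nx;
  int d2 = (axis == 2) ? ny : nz;
  for (int b = 0; b < d2; b++) {
    for (int a = 0; a < d1; a++) {
      long base;
      if (axis == 0)      base = (long)nx * (a + (long)ny * b);
      else if (axis == 1) base = a + (long)nx * ny * b;
      else                base = a + (long)nx * b;
      for (int i = 0; i < n; i++) f[i] = sq[base + stride * i];
      dt1d(f, d, v, z, n, s);
      for (int i = 0; i < n; i++) sq[base + stride * i] = d[i];
    }
  }
}

// distance (um) from every voxel to the nearest TRUE voxel of `mask`
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long N = (long)nx * ny * nz;
  std::vector<double> sq(N);
  for (long i = 0; i < N; i++) sq[i] = mask[i] ? 0.0 : BIG;
  for (int a = 0; a < 3; a++) edt_axis(sq, nx, ny, nz, a, spacing[a]);
  NumericVector out(N);
  for (long i = 0; i < N; i++) out[i] = std::sqrt(sq[i]);
  return out;
}

// ---------------------------------------------------------------------------
// paint the union of balls of `radius` um centred at sample points (um) --
// used to rasterise capillary tubes around sampled centerlines
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
LogicalVector cpp_paint_balls(NumericMatrix pts, double radius,
                              IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long N = (long)nx * ny * nz;
  LogicalVector out(N, false);
  double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  double r2 = radius * radius;
  for (int i = 0; i < pts.nrow(); i++) {
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    int x0 = std::max(0, (int)std::floor((px - radius) / dx - 0.5));
    int x1 = std::min(nx - 1, (int)std::ceil((px + radius) / dx - 0.5));
    int y0 = std::max(0, (int)std::floor((py - radius) / dy - 0.5));
    int y1 = std::min(ny - 1, (int)std::ceil((py + radius) / dy - 0.5));
    int z0 = std::max(0, (int)std::floor((pz - radius) / dz - 0.5));
    int z1 = std::min(nz - 1, (int)std::ceil((pz + radius) / dz - 0.5));
    for (int z = z0; z <= z1; z++) {
      double cz = (z + 0.5) * dz - pz;
      for (int y = y0; y <= y1; y++) {
        double cy = (y + 0.5) * dy - py;
        double rem = r2 - cz * cz - cy * cy;
        if (rem < 0) continue;
        for (int x = x0; x <= x1; x++) {
          double cx = (x + 0.5) * dx - px;
          if (cx * cx <= rem)
            out[x + (long)nx * (y + (long)ny * z)] = true;
        }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// connected components (6- or 26-connectivity), BFS, labels 1..k in scan order
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim,
                          int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long N = (long)nx * ny * nz;
  IntegerVector lab(N, 0);
  std::vector<int> offx, offy, offz;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offx.push_back(dx); offy.push_back(dy); offz.push_back(dz);
      }
  int next = 0;
  std::vector<long> stack;
  for (long start = 0; start < N; start++) {
    if (!mask[start] || lab[start] != 0) continue;
    next++;
    lab[start] = next;
    stack.push_back(start);
    while (!stack.empty()) {
      long p = stack.back();
      stack.pop_back();
      int x = p % nx, y = (p / nx) % ny, z = p / ((long)nx * ny);
      for (size_t j = 0; j < offx.size(); j++) {
        int xx = x + offx[j], yy = y + offy[j], zz = z + offz[j];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        long q = xx + (long)nx * (yy + (long)ny * zz);
        if (mask[q] && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// multi-source Dijkstra region growing (geodesic Voronoi tessellation)
// seeds: label array (>0 at seeds); allowed: growth domain; 6-connectivity
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_region_grow(IntegerVector seeds, LogicalVector allowed,
                              IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long N = (long)nx * ny * nz;
  IntegerVector lab(N, 0);
  std::vector<double> dist(N, BIG);
  typedef std::pair<double, long> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  for (long i = 0; i < N; i++) {
    if (seeds[i] > 0 && allowed[i]) {
      lab[i] = seeds[i];
      dist[i] = 0;
      pq.push(QE(0.0, i));
    }
  }
  int dxs[6] = {-1, 1, 0, 0, 0, 0};
  int dys[6] = {0, 0, -1, 1, 0, 0};
  int dzs[6] = {0, 0, 0, 0, -1, 1};
  double w[6] = {spacing[0], spacing[0], spacing[1], spacing[1],
                 spacing[2], spacing[2]};
  while (!pq.empty()) {
    QE top = pq.top();
    pq.pop();
    long p = top.second;
    if (top.first > dist[p]) continue;
    int x = p % nx, y = (p / nx) % ny, z = p / ((long)nx * ny);
    for (int j = 0; j < 6; j++) {
      int xx = x + dxs[j], yy = y + dys[j], zz = z + dzs[j];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
        continue;
      long q = xx + (long)nx * (yy + (long)ny * zz);
      if (!allowed[q]) continue;
      double nd = dist[p] + w[j];
      if (nd < dist[q] ||
          (nd == dist[q] && lab[p] < lab[q])) { // deterministic tie-break
        dist[q] = nd;
        lab[q] = lab[p];
        pq.push(QE(nd, q));
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// per-voxel surface-area weights (projection estimator). For every exposed
// face between an in-mask voxel and an in-volume out-of-mask 6-neighbour the
// face area is weighted by |n_k|, the axis component of the unit surface
// normal taken from the gradient of the pre-smoothed mask. Exact for planar
// interfaces; faces on the volume boundary are not counted (clipping).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_surface_weights(LogicalVector mask, NumericVector smooth,
                                  IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long N = (long)nx * ny * nz;
  NumericVector w(N, 0.0);
  double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  double faceA[3] = {dy * dz, dx * dz, dx * dy};
  int dxs[3] = {1, 0, 0}, dys[3] = {0, 1, 0}, dzs[3] = {0, 0, 1};

  // central-difference gradient of the smoothed mask, clamped at edges
  auto grad = [&](int x, int y, int z, double g[3]) {
    long p0, p1;
    int xm = std::max(x - 1, 0), xp = std::min(x + 1, nx - 1);
    int ym = std::max(y - 1, 0), yp = std::min(y + 1, ny - 1);
    int zm = std::max(z - 1, 0), zp = std::min(z + 1, nz - 1);
    p0 = xm + (long)nx * (y + (long)ny * z);
    p1 = xp + (long)nx * (y + (long)ny * z);
    g[0] = (smooth[p1] - smooth[p0]) / ((xp - xm) * dx);
    p0 = x + (long)nx * (ym + (long)ny * z);
    p1 = x + (long)nx * (yp + (long)ny * z);
    g[1] = (smooth[p1] - smooth[p0]) / ((yp - ym) * dy);
    p0 = x + (long)nx * (y + (long)ny * zm);
    p1 = x + (long)nx * (y + (long)ny * zp);
    g[2] = (smooth[p1] - smooth[p0]) / ((zp - zm) * dz);
  };

  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        long p = x + (long)nx * (y + (long)ny * z);
        if (!mask[p]) continue;
        for (int a = 0; a < 3; a++)
          for (int sgn = -1; sgn <= 1; sgn += 2) {
            int xx = x + sgn * dxs[a], yy = y + sgn * dys[a],
                zz = z + sgn * dzs[a];
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny ||
                zz >= nz)
              continue; // clip at volume faces
            long q = xx + (long)nx * (yy + (long)ny * zz);
            if (mask[q]) continue;
            double gp[3], gq[3];
            grad(x, y, z, gp);
            grad(xx, yy, zz, gq);
            double g[3] = {0.5 * (gp[0] + gq[0]), 0.5 * (gp[1] + gq[1]),
                           0.5 * (gp[2] + gq[2])};
            double nrm =
                std::sqrt(g[0] * g[0] + g[1] * g[1] + g[2] * g[2]);
            double nk = (nrm < 1e-12) ? 1.0 : std::fabs(g[a]) / nrm;
            w[p] += faceA[a] * nk;
          }
      }
  return w;
}

// ---------------------------------------------------------------------------
// voxels whose 6-neighbourhood (in volume) contains a different label
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
LogicalVector cpp_boundary_mask(IntegerVector lab, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long N = (long)nx * ny * nz;
  LogicalVector out(N, false);
  int dxs[6] = {-1, 1, 0, 0, 0, 0};
  int dys[6] = {0, 0, -1, 1, 0, 0};
  int dzs[6] = {0, 0, 0, 0, -1, 1};
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        long p = x + (long)nx * (y + (long)ny * z);
        for (int j = 0; j < 6; j++) {
          int xx = x + dxs[j], yy = y + dys[j], zz = z + dzs[j];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny ||
              zz >= nz)
            continue;
          long q = xx + (long)nx * (yy + (long)ny * zz);
          if (lab[q] != lab[p]) {
            out[p] = true;
            break;
          }
        }
      }
  return out;
}

// ---------------------------------------------------------------------------
// connected components that never cross label boundaries: every component is
// a maximal connected set of voxels sharing one input label (> 0)
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_label_same3d(IntegerVector lab, IntegerVector dim,
                               int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long N = (long)nx * ny * nz;
  IntegerVector comp(N, 0);
  std::vector<int> offx, offy, offz;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offx.push_back(dx); offy.push_back(dy); offz.push_back(dz);
      }
  int next = 0;
  std::vector<long> stack;
  for (long start = 0; start < N; start++) {
    if (lab[start] <= 0 || comp[start] != 0) continue;
    int target = lab[start];
    next++;
    comp[start] = next;
    stack.push_back(start);
    while (!stack.empty()) {
      long p = stack.back();
      stack.pop_back();
      int x = p % nx, y = (p / nx) % ny, z = p / ((long)nx * ny);
      for (size_t j = 0; j < offx.size(); j++) {
        int xx = x + offx[j], yy = y + offy[j], zz = z + offz[j];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        long q = xx + (long)nx * (yy + (long)ny * zz);
        if (lab[q] == target && comp[q] == 0) {
          comp[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  return comp;
}

// ---------------------------------------------------------------------------
// voxels whose 26-neighbourhood contains >= min_distinct different labels
// with value >= min_label (junctions where several cells meet)
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
LogicalVector cpp_junction_mask(IntegerVector lab, IntegerVector dim,
                                int min_distinct, int min_label) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long N = (long)nx * ny * nz;
  LogicalVector out(N, false);
  std::vector<int> seen;
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        long p = x + (long)nx * (y + (long)ny * z);
        if (lab[p] < min_label) continue;
        seen.clear();
        bool hit = false;
        for (int dz = -1; dz <= 1 && !hit; dz++)
          for (int dy = -1; dy <= 1 && !hit; dy++)
            for (int dx = -1; dx <= 1 && !hit; dx++) {
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny ||
                  zz >= nz)
                continue;
              long q = xx + (long)nx * (yy + (long)ny * zz);
              int l = lab[q];
              if (l < min_label) continue;
              bool known = false;
              for (size_t s = 0; s < seen.size(); s++)
                if (seen[s] == l) { known = true; break; }
              if (!known) {
                seen.push_back(l);
                if ((int)seen.size() >= min_distinct) hit = true;
              }
            }
        if (hit) out[p] = true;
      }
  return out;
}

// ---------------------------------------------------------------------------
// strict local maxima in a box neighbourhood (used on x,y,t difference stacks)
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
LogicalVector cpp_local_max3d(NumericVector vol, IntegerVector dim,
                              IntegerVector rad) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int rx = rad[0], ry = rad[1], rz = rad[2];
  long N = (long)nx * ny * nz;
  LogicalVector out(N, false);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        long p = x + (long)nx * (y + (long)ny * z);
        double v = vol[p];
        bool ismax = true;
        for (int dz = -rz; dz <= rz && ismax; dz++)
          for (int dy = -ry; dy <= ry && ismax; dy++)
            for (int dx = -rx; dx <= rx && ismax; dx++) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny ||
                  zz >= nz)
                continue;
              long q = xx + (long)nx * (yy + (long)ny * zz);
              if (vol[q] > v ||
                  (vol[q] == v && q < p)) // break plateau ties by index
                ismax = false;
            }
        if (ismax) out[p] = true;
      }
  return out;
}
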