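// Geometric primitives used by preprocessing and morphology:
//  - largest inscribed axis-aligned square in a binary mask (DP)
//  - connected constant-level zones (GLSZM support)
//  - separable Gaussian blur and trilinear resampling of 3D arrays
//  - marching-tetrahedra isosurface extraction (watertight by construction)
//  - 3D convex hull (incremental, conflict lists)
//  - Moore-neighbor boundary tracing of a 2D mask

#include <Rcpp.h>
#include <vector>
#include <map>
#include <unordered_map>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// largest inscribed square; ties broken by smallest (row, col) of the
// top-left corner, lexicographically. Returns (row, col, side), 1-based.

// [[Rcpp::export]]
IntegerVector cpp_inscribed_square(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<int> prev(nc, 0), cur(nc, 0);
  int best_side = 0, best_r = -1, best_c = -1;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      int s = 0;
      if (mask(i, j) != 0) {
        if (i == 0 || j == 0) s = 1;
        else {
          s = prev[j];
          if (prev[j - 1] < s) s = prev[j - 1];
          if (cur[j - 1] < s) s = cur[j - 1];
          s += 1;
        }
      }
      cur[j] = s;
      if (s > best_side) {  // strictly greater: keeps first (lex-smallest) top-left
        best_side = s;
        best_r = i - s + 1;
        best_c = j - s + 1;
      }
    }
    std::swap(prev, cur);
  }
  if (best_side == 0) return IntegerVector::create(NA_INTEGER, NA_INTEGER, 0);
  return IntegerVector::create(best_r + 1, best_c + 1, best_side);
}

// ---------------------------------------------------------------------------
// connected zones of equal level; pixels with level < 0 are ignored.
// Returns a two-column matrix (level, size), one row per zone, in
// deterministic scan order.

// [[Rcpp::export]]
IntegerMatrix cpp_zones(IntegerMatrix q, bool conn8) {
  int nr = q.nrow(), nc = q.ncol();
  std::vector<char> seen((size_t)nr * nc, 0);
  std::vector<int> lev, siz, stack;
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  int nnb = conn8 ? 8 : 4;
  const int* dr = conn8 ? dr8 : dr4;
  const int* dc = conn8 ? dc8 : dc4;

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      size_t id = (size_t)j * nr + i;
      if (seen[id] || q(i, j) < 0) continue;
      int level = q(i, j), size = 0;
      stack.clear();
      stack.push_back((int)id);
      seen[id] = 1;
      while (!stack.empty()) {
        int cur = stack.back();
        stack.pop_back();
        ++size;
        int ci = cur % nr, cj = cur / nr;
        for (int t = 0; t < nnb; ++t) {
          int ni = ci + dr[t], nj = cj + dc[t];
          if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
          size_t nid = (size_t)nj * nr + ni;
          if (!seen[nid] && q(ni, nj) == level) {
            seen[nid] = 1;
            stack.push_back((int)nid);
          }
        }
      }
      lev.push_back(level);
      siz.push_back(size);
    }
  }
  IntegerMatrix out((int)lev.size(), 2);
  for (int t = 0; t < (int)lev.size(); ++t) {
    out(t, 0) = lev[t];
    out(t, 1) = siz[t];
  }
  return out;
}

// ---------------------------------------------------------------------------
// separable Gaussian blur of a 3D array (replicate boundary).

static void blur_axis(std::vector<double>& v, int nx, int ny, int nz,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * rad + 1);
  double s = 0.0;
  for (int t = -rad; t <= rad; ++t) {
    ker[t + rad] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += ker[t + rad];
  }
  for (double& k : ker) k /= s;

  int n[3] = {nx, ny, nz};
  size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  int na = n[axis];
  size_t sa = stride[axis];
  std::vector<double> line(na);
  int b1 = axis == 0 ? 1 : 0;
  int b2 = axis == 2 ? 1 : 2;
  for (int i2 = 0; i2 < n[b2]; ++i2) {
    for (int i1 = 0; i1 < n[b1]; ++i1) {
      size_t base = (size_t)i1 * stride[b1] + (size_t)i2 * stride[b2];
      for (int t = 0; t < na; ++t) line[t] = v[base + (size_t)t * sa];
      for (int t = 0; t < na; ++t) {
        double acc = 0.0;
        for (int u = -rad; u <= rad; ++u) {
          int src = t + u;
          if (src < 0) src = 0;
          if (src >= na) src = na - 1;
          acc += ker[u + rad] * line[src];
        }
        v[base + (size_t)t * sa] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_blur3(NumericVector vol, IntegerVector dim,
                              NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> v(vol.begin(), vol.end());
  for (int a = 0; a < 3; ++a) blur_axis(v, nx, ny, nz, a, sigma[a]);
  return NumericVector(v.begin(), v.end());
}

// ---------------------------------------------------------------------------
// trilinear resampling: output voxel o along axis a sits at input
// coordinate o * step[a] (voxel units), clamped to the input grid.

// [[Rcpp::export]]
NumericVector cpp_resample_trilinear(NumericVector vol, IntegerVector dim,
                                     IntegerVector outdim, NumericVector step) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ox = outdim[0], oy = outdim[1], oz = outdim[2];
  NumericVector out((size_t)ox * oy * oz);
  const double* v = vol.begin();
  auto at = [&](int x, int y, int z) -> double {
    return v[(size_t)z * nx * ny + (size_t)y * nx + x];
  };
  size_t idx = 0;
  for (int z = 0; z < oz; ++z) {
    double fz = std::min((double)(nz - 1), z * step[2]);
    int z0 = (int)fz, z1 = std::min(z0 + 1, nz - 1);
    double tz = fz - z0;
    for (int y = 0; y < oy; ++y) {
      double fy = std::min((double)(ny - 1), y * step[1]);
      int y0 = (int)fy, y1 = std::min(y0 + 1, ny - 1);
      double ty = fy - y0;
      for (int x = 0; x < ox; ++x, ++idx) {
        double fx = std::min((double)(nx - 1), x * step[0]);
        int x0 = (int)fx, x1 = std::min(x0 + 1, nx - 1);
        double tx = fx - x0;
        double c00 = at(x0, y0, z0) * (1 - tx) + at(x1, y0, z0) * tx;
        double c10 = at(x0, y1, z0) * (1 - tx) + at(x1, y1, z0) * tx;
        double c01 = at(x0, y0, z1) * (1 - tx) + at(x1, y0, z1) * tx;
        double c11 = at(x0, y1, z1) * (1 - tx) + at(x1, y1, z1) * tx;
        double c0 = c00 * (1 - ty) + c10 * ty;
        double c1 = c01 * (1 - ty) + c11 * ty;
        out[idx] = c0 * (1 - tz) + c1 * tz;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// marching tetrahedra. The cube (x..x+1, y..y+1, z..z+1) is split into six
// tetrahedra sharing the main diagonal; face diagonals agree between
// neighboring cubes, so the triangulated isosurface is watertight.
// Vertices are returned in 0-based voxel coordinates (x, y, z).

// [[Rcpp::export]]
List cpp_march_tets(NumericVector field, IntegerVector dim, double iso) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* f = field.begin();
  auto val = [&](int64_t gid) -> double { return f[gid]; };
  auto gid_of = [&](int x, int y, int z) -> int64_t {
    return (int64_t)z * nx * ny + (int64_t)y * nx + x;
  };

  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
    {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};

  std::unordered_map<uint64_t, int> vmap;
  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;

  auto vertex_on = [&](int64_t a, int64_t b) -> int {
    uint64_t key = (a < b)
      ? ((uint64_t)a << 32) | (uint64_t)(b & 0xffffffff)
      : ((uint64_t)b << 32) | (uint64_t)(a & 0xffffffff);
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double faa = val(a), fbb = val(b);
    double t = (iso - faa) / (fbb - faa);
    if (t < 0) t = 0;
    if (t > 1) t = 1;
    int ax = (int)(a % nx), ay = (int)((a / nx) % ny), az = (int)(a / ((int64_t)nx * ny));
    int bx = (int)(b % nx), by = (int)((b / nx) % ny), bz = (int)(b / ((int64_t)nx * ny));
    int id = (int)vx.size();
    vx.push_back(ax + t * (bx - ax));
    vy.push_back(ay + t * (by - ay));
    vz.push_back(az + t * (bz - az));
    vmap[key] = id;
    return id;
  };

  auto emit = [&](int p1, int p2, int p3, double ix, double iy, double iz) {
    // orient the triangle so its normal points away from the inside point
    double ux = vx[p2] - vx[p1], uy = vy[p2] - vy[p1], uz = vz[p2] - vz[p1];
    double wx = vx[p3] - vx[p1], wy = vy[p3] - vy[p1], wz = vz[p3] - vz[p1];
    double nxv = uy * wz - uz * wy, nyv = uz * wx - ux * wz,
           nzv = ux * wy - uy * wx;
    double cx = (vx[p1] + vx[p2] + vx[p3]) / 3.0 - ix;
    double cy = (vy[p1] + vy[p2] + vy[p3]) / 3.0 - iy;
    double cz = (vz[p1] + vz[p2] + vz[p3]) / 3.0 - iz;
    if (nxv * cx + nyv * cy + nzv * cz < 0) std::swap(p2, p3);
    fa.push_back(p1 + 1);
    fb.push_back(p2 + 1);
    fc.push_back(p3 + 1);
  };

  int64_t corner[8];
  double cval[8];
  for (int z = 0; z + 1 < nz; ++z) {
    for (int y = 0; y + 1 < ny; ++y) {
      for (int x = 0; x + 1 < nx; ++x) {
        for (int v = 0; v < 8; ++v) {
          corner[v] = gid_of(x + (v & 1), y + ((v >> 1) & 1), z + ((v >> 2) & 1));
          cval[v] = val(corner[v]);
        }
        for (int t = 0; t < 6; ++t) {
          int in[4], out[4], ni = 0, no = 0;
          for (int v = 0; v < 4; ++v) {
            int c = tets[t][v];
            if (cval[c] > iso) in[ni++] = c; else out[no++] = c;
          }
          if (ni == 0 || ni == 4) continue;
          // centroid of inside corners (for orientation)
          double ix = 0, iy = 0, iz = 0;
          for (int v = 0; v < ni; ++v) {
            ix += x + (in[v] & 1);
            iy += y + ((in[v] >> 1) & 1);
            iz += z + ((in[v] >> 2) & 1);
          }
          ix /= ni; iy /= ni; iz /= ni;
          if (ni == 1) {
            int p1 = vertex_on(corner[in[0]], corner[out[0]]);
            int p2 = vertex_on(corner[in[0]], corner[out[1]]);
            int p3 = vertex_on(corner[in[0]], corner[out[2]]);
            emit(p1, p2, p3, ix, iy, iz);
          } else if (ni == 3) {
            int p1 = vertex_on(corner[out[0]], corner[in[0]]);
            int p2 = vertex_on(corner[out[0]], corner[in[1]]);
            int p3 = vertex_on(corner[out[0]], corner[in[2]]);
            emit(p1, p2, p3, ix, iy, iz);
          } else {  // ni == 2
            int e1 = vertex_on(corner[in[0]], corner[out[0]]);
            int e2 = vertex_on(corner[in[0]], corner[out[1]]);
            int e3 = vertex_on(corner[in[1]], corner[out[1]]);
            int e4 = vertex_on(corner[in[1]], corner[out[0]]);
            emit(e1, e2, e3, ix, iy, iz);
            emit(e1, e3, e4, ix, iy, iz);
          }
        }
      }
    }
  }

  int nv = (int)vx.size(), nf = (int)fa.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = vx[i];
    V(i, 1) = vy[i];
    V(i, 2) = vz[i];
  }
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = fa[i];
    F(i, 1) = fb[i];
    F(i, 2) = fc[i];
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---------------------------------------------------------------------------
// 3D convex hull, incremental with conflict lists. Points within eps of a
// face plane are treated as interior. Returns volume, surface area, hull
// vertex indices (1-based), and the triangle count.

struct HFace {
  int a, b, c;
  double nx, ny, nz, off;  // outward normal (unnormalized) and offset
  std::vector<int> outside;
  bool alive;
};

// [[Rcpp::export]]
List cpp_convex_hull3(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) stop("hull: need >= 4 points");
  std::vector<double> px(n), py(n), pz(n);
  double lo[3] = {1e300, 1e300, 1e300}, hi[3] = {-1e300, -1e300, -1e300};
  for (int i = 0; i < n; ++i) {
    px[i] = pts(i, 0); py[i] = pts(i, 1); pz[i] = pts(i, 2);
    double c[3] = {px[i], py[i], pz[i]};
    for (int a = 0; a < 3; ++a) {
      if (c[a] < lo[a]) lo[a] = c[a];
      if (c[a] > hi[a]) hi[a] = c[a];
    }
  }
  double diag = std::sqrt((hi[0] - lo[0]) * (hi[0] - lo[0]) +
                          (hi[1] - lo[1]) * (hi[1] - lo[1]) +
                          (hi[2] - lo[2]) * (hi[2] - lo[2]));
  if (diag <= 0) stop("hull: degenerate point set");
  double eps = 1e-9 * diag;

  auto dist = [&](const HFace& F, int p) -> double {
    return F.nx * px[p] + F.ny * py[p] + F.nz * pz[p] - F.off;
  };

  // initial simplex: extreme pair, then max-area, then max-volume
  int i0 = 0, i1 = 0;
  {
    double best = -1;
    int ext[6];
    for (int a = 0; a < 3; ++a) {
      int lo_i = 0, hi_i = 0;
      const std::vector<double>& c = (a == 0 ? px : a == 1 ? py : pz);
      for (int i = 1; i < n; ++i) {
        if (c[i] < c[lo_i]) lo_i = i;
        if (c[i] > c[hi_i]) hi_i = i;
      }
      ext[2 * a] = lo_i; ext[2 * a + 1] = hi_i;
    }
    for (int s = 0; s < 6; ++s)
      for (int t = s + 1; t < 6; ++t) {
        double dx = px[ext[s]] - px[ext[t]], dy = py[ext[s]] - py[ext[t]],
               dz = pz[ext[s]] - pz[ext[t]];
        double d = dx * dx + dy * dy + dz * dz;
        if (d > best) { best = d; i0 = ext[s]; i1 = ext[t]; }
      }
    if (best <= eps * eps) stop("hull: degenerate point set");
  }
  int i2 = -1;
  {
    double best = -1;
    double ux = px[i1] - px[i0], uy = py[i1] - py[i0], uz = pz[i1] - pz[i0];
    for (int i = 0; i < n; ++i) {
      double wx = px[i] - px[i0], wy = py[i] - py[i0], wz = pz[i] - pz[i0];
      double cx = uy * wz - uz * wy, cy = uz * wx - ux * wz, cz = ux * wy - uy * wx;
      double a2 = cx * cx + cy * cy + cz * cz;
      if (a2 > best) { best = a2; i2 = i; }
    }
    if (best <= eps * eps) stop("hull: collinear point set");
  }
  int i3 = -1;
  double nx0, ny0, nz0;
  {
    double ux = px[i1] - px[i0], uy = py[i1] - py[i0], uz = pz[i1] - pz[i0];
    double wx = px[i2] - px[i0], wy = py[i2] - py[i0], wz = pz[i2] - pz[i0];
    nx0 = uy * wz - uz * wy; ny0 = uz * wx - ux * wz; nz0 = ux * wy - uy * wx;
    double best = -1;
    for (int i = 0; i < n; ++i) {
      double d = std::fabs(nx0 * (px[i] - px[i0]) + ny0 * (py[i] - py[i0]) +
                           nz0 * (pz[i] - pz[i0]));
      if (d > best) { best = d; i3 = i; }
    }
    double nlen = std::sqrt(nx0 * nx0 + ny0 * ny0 + nz0 * nz0);
    if (best / nlen <= eps) stop("hull: coplanar point set");
  }

  double icx = (px[i0] + px[i1] + px[i2] + px[i3]) / 4.0;
  double icy = (py[i0] + py[i1] + py[i2] + py[i3]) / 4.0;
  double icz = (pz[i0] + pz[i1] + pz[i2] + pz[i3]) / 4.0;

  std::vector<HFace> faces;
  auto mk_face = [&](int a, int b, int c) {
    HFace F;
    F.a = a; F.b = b; F.c = c;
    double ux = px[b] - px[a], uy = py[b] - py[a], uz = pz[b] - pz[a];
    double wx = px[c] - px[a], wy = py[c] - py[a], wz = pz[c] - pz[a];
    F.nx = uy * wz - uz * wy;
    F.ny = uz * wx - ux * wz;
    F.nz = ux * wy - uy * wx;
    F.off = F.nx * px[a] + F.ny * py[a] + F.nz * pz[a];
    // outward: interior point has negative distance
    if (F.nx * icx + F.ny * icy + F.nz * icz - F.off > 0) {
      std::swap(F.b, F.c);
      F.nx = -F.nx; F.ny = -F.ny; F.nz = -F.nz; F.off = -F.off;
    }
    F.alive = true;
    faces.push_back(F);
  };
  mk_face(i0, i1, i2);
  mk_face(i0, i1, i3);
  mk_face(i0, i2, i3);
  mk_face(i1, i2, i3);

  // conflict lists: normalize eps by face normal length when comparing
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    for (int fidx = 0; fidx < 4; ++fidx) {
      HFace& F = faces[fidx];
      double nlen = std::sqrt(F.nx * F.nx + F.ny * F.ny + F.nz * F.nz);
      if (dist(F, i) > eps * nlen) {
        F.outside.push_back(i);
        break;
      }
    }
  }

  size_t guard = 0, guard_max = (size_t)50 * n + 10000;
  while (true) {
    if (++guard > guard_max) stop("hull: failed to converge");
    int fsel = -1;
    for (int fidx = 0; fidx < (int)faces.size(); ++fidx)
      if (faces[fidx].alive && !faces[fidx].outside.empty()) { fsel = fidx; break; }
    if (fsel < 0) break;
    HFace& FS = faces[fsel];
    double nlenS = std::sqrt(FS.nx * FS.nx + FS.ny * FS.ny + FS.nz * FS.nz);
    int p = FS.outside[0];
    double bestd = -1e300;
    for (int q : FS.outside) {
      double d = dist(FS, q) / nlenS;
      if (d > bestd) { bestd = d; p = q; }
    }

    // visible faces and horizon
    std::vector<int> visible;
    for (int fidx = 0; fidx < (int)faces.size(); ++fidx) {
      HFace& F = faces[fidx];
      if (!F.alive) continue;
      double nlen = std::sqrt(F.nx * F.nx + F.ny * F.ny + F.nz * F.nz);
      if (dist(F, p) > eps * nlen) visible.push_back(fidx);
    }
    std::map<std::pair<int, int>, std::pair<int, int>> edge_count;  // undirected -> (count, directed a,b)
    std::map<std::pair<int, int>, std::pair<int, int>> edge_dir;
    for (int fidx : visible) {
      HFace& F = faces[fidx];
      int e[3][2] = {{F.a, F.b}, {F.b, F.c}, {F.c, F.a}};
      for (int t = 0; t < 3; ++t) {
        int a = e[t][0], b = e[t][1];
        std::pair<int, int> key = a < b ? std::make_pair(a, b) : std::make_pair(b, a);
        auto it = edge_count.find(key);
        if (it == edge_count.end()) edge_count[key] = std::make_pair(1, 0);
        else it->second.first += 1;
        edge_dir[key] = std::make_pair(a, b);
      }
    }
    std::vector<int> orphan;
    for (int fidx : visible) {
      HFace& F = faces[fidx];
      F.alive = false;
      for (int q : F.outside) if (q != p) orphan.push_back(q);
      F.outside.clear();
    }
    std::vector<int> newf;
    for (auto& kv : edge_count) {
      if (kv.second.first != 1) continue;  // interior edge of the visible region
      auto dir = edge_dir[kv.first];
      mk_face(dir.first, dir.second, p);
      newf.push_back((int)faces.size() - 1);
    }
    for (int q : orphan) {
      for (int fidx : newf) {
        HFace& F = faces[fidx];
        double nlen = std::sqrt(F.nx * F.nx + F.ny * F.ny + F.nz * F.nz);
        if (dist(F, q) > eps * nlen) {
          F.outside.push_back(q);
          break;
        }
      }
    }
  }

  double vol = 0.0, area = 0.0;
  std::vector<int> fa, fb, fc;
  std::vector<char> used(n, 0);
  for (const HFace& F : faces) {
    if (!F.alive) continue;
    double nlen = std::sqrt(F.nx * F.nx + F.ny * F.ny + F.nz * F.nz);
    area += nlen / 2.0;
    // signed tet volume against the interior point
    double ax = px[F.a] - icx, ay = py[F.a] - icy, az = pz[F.a] - icz;
    double bx2 = px[F.b] - icx, by2 = py[F.b] - icy, bz2 = pz[F.b] - icz;
    double cx2 = px[F.c] - icx, cy2 = py[F.c] - icy, cz2 = pz[F.c] - icz;
    vol += (ax * (by2 * cz2 - bz2 * cy2) - ay * (bx2 * cz2 - bz2 * cx2) +
            az * (bx2 * cy2 - by2 * cx2)) / 6.0;
    used[F.a] = used[F.b] = used[F.c] = 1;
    fa.push_back(F.a + 1);
    fb.push_back(F.b + 1);
    fc.push_back(F.c + 1);
  }
  std::vector<int> hv;
  for (int i = 0; i < n; ++i) if (used[i]) hv.push_back(i + 1);
  IntegerMatrix F((int)fa.size(), 3);
  for (int i = 0; i < (int)fa.size(); ++i) {
    F(i, 0) = fa[i]; F(i, 1) = fb[i]; F(i, 2) = fc[i];
  }
  return List::create(_["volume"] = vol, _["area"] = area,
                      _["vertices"] = IntegerVector(hv.begin(), hv.end()),
                      _["faces"] = F);
}

// ---------------------------------------------------------------------------
// Moore-neighbor boundary tracing; returns ordered boundary pixels
// (row, col), 1-based. The mask is assumed to hold one 8-connected blob.

// [[Rcpp::export]]
IntegerMatrix cpp_trace_boundary(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  auto at = [&](int r, int c) -> int {
    if (r < 0 || c < 0 || r >= nr || c >= nc) return 0;
    return mask(r, c) != 0 ? 1 : 0;
  };
  int sr = -1, sc = -1;
  for (int r = 0; r < nr && sr < 0; ++r)
    for (int c = 0; c < nc; ++c)
      if (mask(r, c) != 0) { sr = r; sc = c; break; }
  if (sr < 0) stop("trace: empty mask");

  // clockwise Moore neighborhood starting at W
  const int dr[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int dc[8] = {-1, -1, 0, 1, 1, 1, 0, -1};

  std::vector<int> br, bc;
  br.push_back(sr); bc.push_back(sc);

  // isolated pixel?
  bool iso = true;
  for (int t = 0; t < 8; ++t) if (at(sr + dr[t], sc + dc[t])) iso = false;
  if (!iso) {
    int pr = sr, pc = sc;
    int back = 0;  // backtrack direction index; W of the start is background
    long cap = 4L * nr * nc + 16;
    while (cap-- > 0) {
      int found = -1, prev_d = back;
      for (int t = 1; t <= 8; ++t) {
        int d = (back + t) % 8;
        if (at(pr + dr[d], pc + dc[d])) { found = d; break; }
        prev_d = d;
      }
      if (found < 0) break;
      // last background examined becomes the new backtrack pixel
      int brr = pr + dr[prev_d], bcc = pc + dc[prev_d];
      int qr = pr + dr[found], qc = pc + dc[found];
      int nb = 0;
      for (int u = 0; u < 8; ++u)
        if (qr + dr[u] == brr && qc + dc[u] == bcc) { nb = u; break; }
      back = nb;
      pr = qr; pc = qc;
      if (pr == sr && pc == sc) break;
      br.push_back(pr); bc.push_back(pc);
    }
  }
  IntegerMatrix out((int)br.size(), 2);
  for (int i = 0; i < (int)br.size(); ++i) {
    out(i, 0) = br[i] + 1;
    out(i, 1) = bc[i] + 1;
  }
  return out;
}
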