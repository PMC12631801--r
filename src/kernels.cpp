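#include <Rcpp.h>
#include <queue>
#include <set>
#include <utility>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Arrays are stored R-style (column major) with axis order (Z, Y, X):
// linear index = z + nz*y + nz*ny*x.

static inline int lin_idx(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// 26-connectivity connected components. Labels are assigned in raster order
// (Z slowest, then Y, then X fastest) of each component's first voxel, so the
// labeling is deterministic and permutation-free.
// [[Rcpp::export]]
IntegerVector cpp_label_cc26(const LogicalVector& grid, const IntegerVector& dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  IntegerVector labels(grid.size(), 0);
  int next_label = 0;
  std::vector<int> stack;
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        const int idx = lin_idx(z, y, x, nz, ny);
        if (!grid[idx] || labels[idx] != 0) continue;
        ++next_label;
        labels[idx] = next_label;
        stack.clear();
        stack.push_back(idx);
        while (!stack.empty()) {
          const int cur = stack.back();
          stack.pop_back();
          const int cz = cur % nz;
          const int rem = cur / nz;
          const int cy = rem % ny;
          const int cx = rem / ny;
          for (int dz = -1; dz <= 1; ++dz) {
            const int zz = cz + dz;
            if (zz < 0 || zz >= nz) continue;
            for (int dy = -1; dy <= 1; ++dy) {
              const int yy = cy + dy;
              if (yy < 0 || yy >= ny) continue;
              for (int dx = -1; dx <= 1; ++dx) {
                if (dz == 0 && dy == 0 && dx == 0) continue;
                const int xx = cx + dx;
                if (xx < 0 || xx >= nx) continue;
                const int nidx = lin_idx(zz, yy, xx, nz, ny);
                if (grid[nidx] && labels[nidx] == 0) {
                  labels[nidx] = next_label;
                  stack.push_back(nidx);
                }
              }
            }
          }
        }
      }
    }
  }
  labels.attr("n_labels") = next_label;
  return labels;
}

// ---------------------------------------------------------------------------
// Surface area by marching tetrahedra on a scalar field.
// Each cell of 8 voxel corners is split into 6 tetrahedra sharing the main
// diagonal; the iso-surface is extracted per tetrahedron with linear
// interpolation along edges and triangle areas are accumulated in physical
// units. Corner bit order within a cell: k = dx + 2*dy + 4*dz.

static const int TETS[6][4] = {
  {0, 1, 5, 7}, {0, 5, 4, 7}, {0, 4, 6, 7},
  {0, 6, 2, 7}, {0, 2, 3, 7}, {0, 3, 1, 7}
};

static inline double tri_area(const double* a, const double* b, const double* c) {
  const double u0 = b[0] - a[0], u1 = b[1] - a[1], u2 = b[2] - a[2];
  const double v0 = c[0] - a[0], v1 = c[1] - a[1], v2 = c[2] - a[2];
  const double cx = u1 * v2 - u2 * v1;
  const double cy = u2 * v0 - u0 * v2;
  const double cz = u0 * v1 - u1 * v0;
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// [[Rcpp::export]]
double cpp_marching_area(const NumericVector& vol, const IntegerVector& dims,
                         const NumericVector& spacing, double iso) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  double total = 0.0;
  double corner[8][3];  // physical coords (z, y, x)
  double val[8];
  for (int z = 0; z + 1 < nz; ++z) {
    for (int y = 0; y + 1 < ny; ++y) {
      for (int x = 0; x + 1 < nx; ++x) {
        bool any_in = false, any_out = false;
        for (int k = 0; k < 8; ++k) {
          const int dx = k & 1, dy = (k >> 1) & 1, dz = (k >> 2) & 1;
          val[k] = vol[lin_idx(z + dz, y + dy, x + dx, nz, ny)];
          corner[k][0] = (z + dz) * sz;
          corner[k][1] = (y + dy) * sy;
          corner[k][2] = (x + dx) * sx;
          if (val[k] > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int in_ids[4], out_ids[4];
          int n_in = 0, n_out = 0;
          for (int j = 0; j < 4; ++j) {
            const int k = TETS[t][j];
            if (val[k] > iso) in_ids[n_in++] = k; else out_ids[n_out++] = k;
          }
          if (n_in == 0 || n_in == 4) continue;
          // interpolated point on edge (a inside, b outside)
          double pt[4][3];
          int npts = 0;
          if (n_in == 1 || n_in == 3) {
            const int apex = (n_in == 1) ? in_ids[0] : out_ids[0];
            const int* others = (n_in == 1) ? out_ids : in_ids;
            for (int j = 0; j < 3; ++j) {
              const int b = others[j];
              const double tt = (iso - val[apex]) / (val[b] - val[apex]);
              for (int d = 0; d < 3; ++d)
                pt[npts][d] = corner[apex][d] + tt * (corner[b][d] - corner[apex][d]);
              ++npts;
            }
            total += tri_area(pt[0], pt[1], pt[2]);
          } else {  // 2 in, 2 out -> quad, cyclic order (ac, ad, bd, bc)
            const int a = in_ids[0], b = in_ids[1];
            const int c = out_ids[0], d = out_ids[1];
            const int pairs[4][2] = {{a, c}, {a, d}, {b, d}, {b, c}};
            for (int j = 0; j < 4; ++j) {
              const int p = pairs[j][0], q = pairs[j][1];
              const double tt = (iso - val[p]) / (val[q] - val[p]);
              for (int dd = 0; dd < 3; ++dd)
                pt[j][dd] = corner[p][dd] + tt * (corner[q][dd] - corner[p][dd]);
            }
            total += tri_area(pt[0], pt[1], pt[2]) + tri_area(pt[0], pt[2], pt[3]);
          }
        }
      }
    }
  }
  return total;
}

// ---------------------------------------------------------------------------
// Incremental 3D convex hull + point membership (convex image).
// Returns list(status, inside): status 1 flags a degenerate (rank < 3) input,
// which the R caller handles separately.

struct Face {
  int a, b, c;
  double nx, ny, nz, off;
  bool alive;
};

static inline void face_plane(Face& f, const std::vector<double>& px,
                              const std::vector<double>& py,
                              const std::vector<double>& pz) {
  const double ux = px[f.b] - px[f.a], uy = py[f.b] - py[f.a], uz = pz[f.b] - pz[f.a];
  const double vx = px[f.c] - px[f.a], vy = py[f.c] - py[f.a], vz = pz[f.c] - pz[f.a];
  double nx = uy * vz - uz * vy;
  double ny = uz * vx - ux * vz;
  double nz = ux * vy - uy * vx;
  const double nrm = std::sqrt(nx * nx + ny * ny + nz * nz);
  if (nrm > 0) { nx /= nrm; ny /= nrm; nz /= nrm; }
  f.nx = nx; f.ny = ny; f.nz = nz;
  f.off = nx * px[f.a] + ny * py[f.a] + nz * pz[f.a];
}

// build hull faces; returns false when the input is degenerate (rank < 3)
static bool build_hull(const NumericMatrix& pts, std::vector<Face>& out_faces) {
  const int n = pts.nrow();
  if (n < 4) return false;
  std::vector<double> px(n), py(n), pz(n);
  for (int i = 0; i < n; ++i) { px[i] = pts(i, 0); py[i] = pts(i, 1); pz[i] = pts(i, 2); }

  double scale = 1.0;
  {
    double lo[3] = {px[0], py[0], pz[0]}, hi[3] = {px[0], py[0], pz[0]};
    for (int i = 1; i < n; ++i) {
      lo[0] = std::min(lo[0], px[i]); hi[0] = std::max(hi[0], px[i]);
      lo[1] = std::min(lo[1], py[i]); hi[1] = std::max(hi[1], py[i]);
      lo[2] = std::min(lo[2], pz[i]); hi[2] = std::max(hi[2], pz[i]);
    }
    scale = std::max(1.0, std::max(hi[0] - lo[0], std::max(hi[1] - lo[1], hi[2] - lo[2])));
  }
  const double eps = 1e-9 * scale;

  // initial tetrahedron from extreme points
  int i0 = 0;
  for (int i = 1; i < n; ++i)
    if (px[i] < px[i0] || (px[i] == px[i0] && (py[i] < py[i0] ||
        (py[i] == py[i0] && pz[i] < pz[i0])))) i0 = i;
  int i1 = -1; double best = -1.0;
  for (int i = 0; i < n; ++i) {
    const double d = (px[i]-px[i0])*(px[i]-px[i0]) + (py[i]-py[i0])*(py[i]-py[i0]) +
                     (pz[i]-pz[i0])*(pz[i]-pz[i0]);
    if (d > best) { best = d; i1 = i; }
  }
  if (best <= eps * eps) return false;
  int i2 = -1; best = -1.0;
  {
    const double ax = px[i1]-px[i0], ay = py[i1]-py[i0], az = pz[i1]-pz[i0];
    for (int i = 0; i < n; ++i) {
      const double bx = px[i]-px[i0], by = py[i]-py[i0], bz = pz[i]-pz[i0];
      const double cx = ay*bz - az*by, cy = az*bx - ax*bz, cz = ax*by - ay*bx;
      const double d = cx*cx + cy*cy + cz*cz;
      if (d > best) { best = d; i2 = i; }
    }
  }
  if (best <= eps * eps * scale * scale) return false;
  Face f0; f0.a = i0; f0.b = i1; f0.c = i2; f0.alive = true;
  face_plane(f0, px, py, pz);
  int i3 = -1; best = -1.0;
  for (int i = 0; i < n; ++i) {
    const double d = std::fabs(f0.nx*px[i] + f0.ny*py[i] + f0.nz*pz[i] - f0.off);
    if (d > best) { best = d; i3 = i; }
  }
  if (best <= eps) return false;

  const double cx0 = (px[i0]+px[i1]+px[i2]+px[i3]) / 4.0;
  const double cy0 = (py[i0]+py[i1]+py[i2]+py[i3]) / 4.0;
  const double cz0 = (pz[i0]+pz[i1]+pz[i2]+pz[i3]) / 4.0;

  std::vector<Face> faces;
  const int tet[4][3] = {{i0,i1,i2},{i0,i1,i3},{i0,i2,i3},{i1,i2,i3}};
  for (int t = 0; t < 4; ++t) {
    Face f; f.a = tet[t][0]; f.b = tet[t][1]; f.c = tet[t][2]; f.alive = true;
    face_plane(f, px, py, pz);
    if (f.nx*cx0 + f.ny*cy0 + f.nz*cz0 - f.off > 0) {  // flip outward
      std::swap(f.b, f.c);
      face_plane(f, px, py, pz);
    }
    faces.push_back(f);
  }

  const double epsv = 1e-7 * scale;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    std::vector<int> visible;
    for (size_t j = 0; j < faces.size(); ++j) {
      if (!faces[j].alive) continue;
      if (faces[j].nx*px[i] + faces[j].ny*py[i] + faces[j].nz*pz[i] - faces[j].off > epsv)
        visible.push_back((int)j);
    }
    if (visible.empty()) continue;
    std::set<std::pair<int,int> > vis_edges;
    for (size_t v = 0; v < visible.size(); ++v) {
      const Face& f = faces[visible[v]];
      vis_edges.insert(std::make_pair(f.a, f.b));
      vis_edges.insert(std::make_pair(f.b, f.c));
      vis_edges.insert(std::make_pair(f.c, f.a));
    }
    std::vector<std::pair<int,int> > horizon;
    for (std::set<std::pair<int,int> >::const_iterator it = vis_edges.begin();
         it != vis_edges.end(); ++it) {
      if (vis_edges.find(std::make_pair(it->second, it->first)) == vis_edges.end())
        horizon.push_back(*it);
    }
    for (size_t v = 0; v < visible.size(); ++v) faces[visible[v]].alive = false;
    for (size_t h = 0; h < horizon.size(); ++h) {
      Face f; f.a = horizon[h].first; f.b = horizon[h].second; f.c = i; f.alive = true;
      face_plane(f, px, py, pz);
      if (f.nx*cx0 + f.ny*cy0 + f.nz*cz0 - f.off > 0) {
        std::swap(f.b, f.c);
        face_plane(f, px, py, pz);
      }
      faces.push_back(f);
    }
  }

  out_faces.clear();
  for (size_t j = 0; j < faces.size(); ++j)
    if (faces[j].alive) out_faces.push_back(faces[j]);
  return true;
}

// [[Rcpp::export]]
List cpp_convex_image(const NumericMatrix& pts, const NumericMatrix& queries,
                      double tol) {
  LogicalVector inside(queries.nrow());
  std::vector<Face> faces;
  if (!build_hull(pts, faces)) {
    return List::create(_["status"] = 1, _["inside"] = inside);
  }
  for (int q = 0; q < queries.nrow(); ++q) {
    const double q0 = queries(q, 0), q1 = queries(q, 1), q2 = queries(q, 2);
    bool in = true;
    for (size_t j = 0; j < faces.size(); ++j) {
      const Face& f = faces[j];
      if (f.nx*q0 + f.ny*q1 + f.nz*q2 - f.off > tol) { in = false; break; }
    }
    inside[q] = in;
  }
  return List::create(_["status"] = 0, _["inside"] = inside);
}

// Count integer lattice points inside the hull of pts within the inclusive
// bounding box lo..hi (coordinates ordered (z, y, x) like the points). For
// each (z, y) row the facet inequalities reduce to an interval in x, so the
// cost is O(rows * faces) instead of O(voxels * faces).
// [[Rcpp::export]]
double cpp_hull_lattice_count(const NumericMatrix& pts,
                              const IntegerVector& lo,
                              const IntegerVector& hi, double tol) {
  std::vector<Face> faces;
  if (!build_hull(pts, faces)) return -1.0;
  double count = 0.0;
  for (int z = lo[0]; z <= hi[0]; ++z) {
    for (int y = lo[1]; y <= hi[1]; ++y) {
      double xlo = lo[2], xhi = hi[2];
      bool feasible = true;
      for (size_t j = 0; j < faces.size() && feasible; ++j) {
        const Face& f = faces[j];
        const double a = f.nz;  // coefficient of x (third coordinate)
        const double b = f.nx * z + f.ny * y - f.off - tol;
        if (a > 1e-12) {
          xhi = std::min(xhi, -b / a);
        } else if (a < -1e-12) {
          xlo = std::max(xlo, -b / a);
        } else if (b > 0) {
          feasible = false;
        }
      }
      if (!feasible) continue;
      const double ilo = std::ceil(xlo - 1e-9);
      const double ihi = std::floor(xhi + 1e-9);
      if (ihi >= ilo) count += ihi - ilo + 1;
    }
  }
  return count;
}
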