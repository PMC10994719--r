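#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Voxel occupancy-grid utilities for topological (protein-volume-avoiding)
// distances. Voxels are indexed 0-based here; the R wrappers convert.

static inline int vox(double w, double origin, double spacing) {
  return (int) std::floor((w - origin) / spacing + 0.5);
}

// Mark voxels whose center lies within r[i] of atom i. Carve-out spheres of
// clearance radius around each endpoint stay free regardless of atoms.
// [[Rcpp::export(name = ".grid_block_cpp")]]
LogicalVector grid_block_cpp(NumericVector origin, double spacing,
                             IntegerVector dim, NumericMatrix atoms,
                             NumericVector radii, NumericMatrix clear_pts,
                             double clearance) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector blocked((R_xlen_t) nx * ny * nz, false);
  for (int a = 0; a < atoms.nrow(); ++a) {
    double r = radii[a], r2 = r * r;
    double ax = atoms(a, 0), ay = atoms(a, 1), az = atoms(a, 2);
    int i0 = std::max(0, (int) std::floor((ax - r - origin[0]) / spacing));
    int i1 = std::min(nx - 1, (int) std::ceil((ax + r - origin[0]) / spacing));
    int j0 = std::max(0, (int) std::floor((ay - r - origin[1]) / spacing));
    int j1 = std::min(ny - 1, (int) std::ceil((ay + r - origin[1]) / spacing));
    int k0 = std::max(0, (int) std::floor((az - r - origin[2]) / spacing));
    int k1 = std::min(nz - 1, (int) std::ceil((az + r - origin[2]) / spacing));
    for (int i = i0; i <= i1; ++i) {
      double dx = origin[0] + i * spacing - ax;
      for (int j = j0; j <= j1; ++j) {
        double dy = origin[1] + j * spacing - ay;
        for (int k = k0; k <= k1; ++k) {
          double dz = origin[2] + k * spacing - az;
          if (dx * dx + dy * dy + dz * dz <= r2)
            blocked[(R_xlen_t) i + (R_xlen_t) nx * (j + (R_xlen_t) ny * k)] = true;
        }
      }
    }
  }
  const double c2 = clearance * clearance;
  for (int p = 0; p < clear_pts.nrow(); ++p) {
    double px = clear_pts(p, 0), py = clear_pts(p, 1), pz = clear_pts(p, 2);
    int i0 = std::max(0, (int) std::floor((px - clearance - origin[0]) / spacing));
    int i1 = std::min(nx - 1, (int) std::ceil((px + clearance - origin[0]) / spacing));
    int j0 = std::max(0, (int) std::floor((py - clearance - origin[1]) / spacing));
    int j1 = std::min(ny - 1, (int) std::ceil((py + clearance - origin[1]) / spacing));
    int k0 = std::max(0, (int) std::floor((pz - clearance - origin[2]) / spacing));
    int k1 = std::min(nz - 1, (int) std::ceil((pz + clearance - origin[2]) / spacing));
    for (int i = i0; i <= i1; ++i) {
      double dx = origin[0] + i * spacing - px;
      for (int j = j0; j <= j1; ++j) {
        double dy = origin[1] + j * spacing - py;
        for (int k = k0; k <= k1; ++k) {
          double dz = origin[2] + k * spacing - pz;
          if (dx * dx + dy * dy + dz * dz <= c2)
            blocked[(R_xlen_t) i + (R_xlen_t) nx * (j + (R_xlen_t) ny * k)] = false;
        }
      }
    }
  }
  return blocked;
}

// Dijkstra over the 26-connected free-voxel graph; step cost
// spacing * sqrt(dx^2+dy^2+dz^2). Returns c(distance, capped):
// distance = Inf when no path of length <= cap exists; capped = 1 when the
// search was abandoned at the cap (as opposed to exhausting the component).
// [[Rcpp::export(name = ".grid_dijkstra_cpp")]]
NumericVector grid_dijkstra_cpp(LogicalVector blocked, IntegerVector dim,
                                IntegerVector start, IntegerVector goal,
                                double spacing, double cap) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t N = (R_xlen_t) nx * ny * nz;
  auto idx = [&](int i, int j, int k) {
    return (R_xlen_t) i + (R_xlen_t) nx * (j + (R_xlen_t) ny * k);
  };
  R_xlen_t s = idx(start[0], start[1], start[2]);
  R_xlen_t g = idx(goal[0], goal[1], goal[2]);
  if (blocked[s] || blocked[g])
    return NumericVector::create(R_PosInf, 0.0);
  if (s == g) return NumericVector::create(0.0, 0.0);

  int off[26][3]; double cost[26]; int no = 0;
  for (int di = -1; di <= 1; ++di)
    for (int dj = -1; dj <= 1; ++dj)
      for (int dk = -1; dk <= 1; ++dk) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        off[no][0] = di; off[no][1] = dj; off[no][2] = dk;
        cost[no] = spacing * std::sqrt((double) (di * di + dj * dj + dk * dk));
        ++no;
      }

  std::vector<double> dist(N, R_PosInf);
  typedef std::pair<double, R_xlen_t> Q;
  std::priority_queue<Q, std::vector<Q>, std::greater<Q> > pq;
  dist[s] = 0.0;
  pq.push(Q(0.0, s));
  bool capped = false;
  while (!pq.empty()) {
    Q top = pq.top(); pq.pop();
    double d = top.first; R_xlen_t u = top.second;
    if (d > dist[u]) continue;
    if (u == g) return NumericVector::create(d, 0.0);
    if (d > cap) { capped = true; break; }
    int k = (int) (u / ((R_xlen_t) nx * ny));
    int rem = (int) (u - (R_xlen_t) k * nx * ny);
    int j = rem / nx, i = rem % nx;
    for (int o = 0; o < no; ++o) {
      int ii = i + off[o][0], jj = j + off[o][1], kk = k + off[o][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      R_xlen_t v = idx(ii, jj, kk);
      if (blocked[v]) continue;
      double nd = d + cost[o];
      if (nd < dist[v]) { dist[v] = nd; pq.push(Q(nd, v)); }
    }
  }
  return NumericVector::create(R_PosInf, capped ? 1.0 : 0.0);
}

// TRUE when the straight segment a-b passes only through free voxels.
// [[Rcpp::export(name = ".segment_free_cpp")]]
bool segment_free_cpp(LogicalVector blocked, NumericVector origin,
                      double spacing, IntegerVector dim,
                      NumericVector a, NumericVector b) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  double len = std::sqrt((a[0] - b[0]) * (a[0] - b[0]) +
                         (a[1] - b[1]) * (a[1] - b[1]) +
                         (a[2] - b[2]) * (a[2] - b[2]));
  int nstep = std::max(1, (int) std::ceil(len / (spacing * 0.25)));
  for (int sdx = 0; sdx <= nstep; ++sdx) {
    double f = (double) sdx / nstep;
    double x = a[0] + f * (b[0] - a[0]);
    double y = a[1] + f * (b[1] - a[1]);
    double z = a[2] + f * (b[2] - a[2]);
    int i = vox(x, origin[0], spacing);
    int j = vox(y, origin[1], spacing);
    int k = vox(z, origin[2], spacing);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return false;
    if (blocked[(R_xlen_t) i + (R_xlen_t) nx * (j + (R_xlen_t) ny * k)])
      return false;
  }
  return true;
}
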