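#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Off-lattice particle-cluster diffusion-limited aggregation.
//
// Seed monomer at the origin. Each subsequent monomer is released from a
// uniformly random point on a launch sphere just outside the cluster and
// performs an isotropic random walk with step length equal to the monomer
// radius. On contact (center distance <= 2r to any cluster monomer) the
// walker is backtracked along its last step to the exact 2r contact
// distance and sticks (probability 1). Walkers beyond the kill radius
// (3 x launch radius) are relaunched. Far from the cluster the walker takes
// a single long step of length (d - R_cluster - 2r); an isotropic step of
// any length from a point outside a sphere not containing the cluster is
// distributionally equivalent to many short steps, so this is an exact
// acceleration, not an approximation.
//
// Randomness comes from R's RNG (unif_rand/norm_rand), so results are fully
// determined by set.seed() on the R side.

namespace {

struct Grid {
  double cell;
  std::unordered_map<long long, std::vector<int> > cells;

  explicit Grid(double cell_size) : cell(cell_size) {}

  long long key(double x, double y, double z) const {
    long long ix = (long long)std::floor(x / cell);
    long long iy = (long long)std::floor(y / cell);
    long long iz = (long long)std::floor(z / cell);
    // pack with offsets; clusters never come near 2^20 cells across
    return ((ix + (1 << 20)) << 42) | ((iy + (1 << 20)) << 21) |
           (iz + (1 << 20));
  }

  void insert(int id, const double* p) {
    cells[key(p[0], p[1], p[2])].push_back(id);
  }

  // collect monomer ids in the 27 cells around p
  void neighbors(const double* p, std::vector<int>& out) const {
    out.clear();
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          long long k = key(p[0] + a * cell, p[1] + b * cell,
                            p[2] + c * cell);
          std::unordered_map<long long, std::vector<int> >::const_iterator
              it = cells.find(k);
          if (it != cells.end())
            out.insert(out.end(), it->second.begin(), it->second.end());
        }
  }
};

// boolean occupancy grid: marks cells containing at least one monomer;
// an empty 27-cell block around p certifies no monomer within `cell` of p
struct CoarseGrid {
  double cell;
  std::unordered_set<long long> occ;

  explicit CoarseGrid(double cell_size) : cell(cell_size) {}

  long long key(double x, double y, double z) const {
    long long ix = (long long)std::floor(x / cell);
    long long iy = (long long)std::floor(y / cell);
    long long iz = (long long)std::floor(z / cell);
    return ((ix + (1 << 20)) << 42) | ((iy + (1 << 20)) << 21) |
           (iz + (1 << 20));
  }

  void insert(const double* p) { occ.insert(key(p[0], p[1], p[2])); }

  bool block_empty(const double* p) const {
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c)
          if (occ.count(key(p[0] + a * cell, p[1] + b * cell,
                            p[2] + c * cell)))
            return false;
    return true;
  }
};

inline void rand_dir(double* d) {
  double n2 = 0;
  do {
    d[0] = norm_rand(); d[1] = norm_rand(); d[2] = norm_rand();
    n2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
  } while (n2 < 1e-12);
  double inv = 1.0 / std::sqrt(n2);
  d[0] *= inv; d[1] *= inv; d[2] *= inv;
}

}  // namespace

// [[Rcpp::export(name = ".dla_cpp")]]
NumericMatrix dla_cpp(int n_monomers, double r) {
  if (n_monomers < 2) stop("n_monomers must be >= 2");
  if (r <= 0) stop("monomer radius must be positive");
  RNGScope scope;

  const double contact = 2.0 * r;
  const double contact2 = contact * contact;
  std::vector<double> pts;
  pts.reserve(3 * n_monomers);
  pts.push_back(0); pts.push_back(0); pts.push_back(0);
  // cell = 3r: any monomer reachable within a short step (distance
  // <= 2r + step = 3r from the step start) lies in the 27-cell block
  Grid grid(3.0 * r);
  // coarser occupancy grids let walkers in empty space inside the cluster
  // envelope take provably contact-free long steps
  CoarseGrid mid(9.0 * r), coarse(27.0 * r);
  double p0[3] = { 0, 0, 0 };
  grid.insert(0, p0);
  mid.insert(p0);
  coarse.insert(p0);
  double r_max = 0;  // max center distance from origin
  std::vector<int> nb;

  for (int m = 1; m < n_monomers; ++m) {
    const double launch = r_max + 5.0 * r;
    const double kill = 3.0 * launch;
    double pos[3], dir[3];
    rand_dir(dir);
    pos[0] = launch * dir[0]; pos[1] = launch * dir[1];
    pos[2] = launch * dir[2];
    bool stuck = false;
    while (!stuck) {
      double d = std::sqrt(pos[0] * pos[0] + pos[1] * pos[1] +
                           pos[2] * pos[2]);
      if (d > kill) {  // escaped: relaunch
        rand_dir(dir);
        pos[0] = launch * dir[0]; pos[1] = launch * dir[1];
        pos[2] = launch * dir[2];
        continue;
      }
      double step;
      bool check = false;
      double gap = d - r_max - contact;
      if (gap > r) {
        // outside the envelope: a jump of length (d - r_max - 2r) cannot
        // bring any point of the path closer than 2r to the cluster
        step = gap;
      } else {
        grid.neighbors(pos, nb);
        if (!nb.empty()) {
          step = r; check = true;          // contact possible this step
        } else if (!mid.block_empty(pos)) {
          step = r;                        // nearest monomer > 3r: safe
        } else if (!coarse.block_empty(pos)) {
          step = 0.99 * (9.0 * r - contact);   // nearest > 9r
        } else {
          step = 0.99 * (27.0 * r - contact);  // nearest > 27r
        }
      }
      rand_dir(dir);
      double npos[3] = { pos[0] + step * dir[0], pos[1] + step * dir[1],
                         pos[2] + step * dir[2] };
      if (check) {
        // find earliest contact along the segment
        double best_t = 2.0;
        for (size_t q = 0; q < nb.size(); ++q) {
          const double* c = &pts[3 * nb[q]];
          // |pos + t*step*dir - c|^2 = contact^2, t in (0,1]
          double w[3] = { pos[0] - c[0], pos[1] - c[1], pos[2] - c[2] };
          double b = w[0] * dir[0] + w[1] * dir[1] + w[2] * dir[2];
          double cc = w[0] * w[0] + w[1] * w[1] + w[2] * w[2] - contact2;
          double disc = b * b - cc;  // per unit step length
          if (disc < 0) continue;
          double t = (-b - std::sqrt(disc)) / step;
          if (t >= 0 && t <= 1.0 && t < best_t) best_t = t;
        }
        if (best_t <= 1.0) {
          double fin[3] = { pos[0] + best_t * step * dir[0],
                            pos[1] + best_t * step * dir[1],
                            pos[2] + best_t * step * dir[2] };
          pts.push_back(fin[0]); pts.push_back(fin[1]); pts.push_back(fin[2]);
          grid.insert(m, fin);
          mid.insert(fin);
          coarse.insert(fin);
          double fd = std::sqrt(fin[0] * fin[0] + fin[1] * fin[1] +
                                fin[2] * fin[2]);
          if (fd > r_max) r_max = fd;
          stuck = true;
          continue;
        }
      }
      pos[0] = npos[0]; pos[1] = npos[1]; pos[2] = npos[2];
    }
  }

  NumericMatrix out(n_monomers, 3);
  for (int i = 0; i < n_monomers; ++i) {
    out(i, 0) = pts[3 * i];
    out(i, 1) = pts[3 * i + 1];
    out(i, 2) = pts[3 * i + 2];
  }
  return out;
}
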