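// Cell-list accelerated kernels: exact atom-pair contact counting and
// Shrake-Rupley SASA point burial. Cell lists fall back to brute force
// when the grid would be degenerate or tiny.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct CellGrid {
  double ox, oy, oz, edge;
  int nx, ny, nz;
  std::vector<std::vector<int>> cells;

  CellGrid(const NumericMatrix& pts, double edge_) : edge(edge_) {
    ox = oy = oz = R_PosInf;
    double mx = R_NegInf, my = R_NegInf, mz = R_NegInf;
    for (int i = 0; i < pts.nrow(); ++i) {
      ox = std::min(ox, pts(i, 0)); mx = std::max(mx, pts(i, 0));
      oy = std::min(oy, pts(i, 1)); my = std::max(my, pts(i, 1));
      oz = std::min(oz, pts(i, 2)); mz = std::max(mz, pts(i, 2));
    }
    nx = (int)std::floor((mx - ox) / edge) + 1;
    ny = (int)std::floor((my - oy) / edge) + 1;
    nz = (int)std::floor((mz - oz) / edge) + 1;
    cells.assign((size_t)nx * ny * nz, {});
    for (int i = 0; i < pts.nrow(); ++i)
      cells[index(pts(i, 0), pts(i, 1), pts(i, 2))].push_back(i);
  }
  size_t index(double x, double y, double z) const {
    int ix = std::min(nx - 1, (int)std::floor((x - ox) / edge));
    int iy = std::min(ny - 1, (int)std::floor((y - oy) / edge));
    int iz = std::min(nz - 1, (int)std::floor((z - oz) / edge));
    return ((size_t)ix * ny + iy) * nz + iz;
  }
  template <class F>
  void neighbors(double x, double y, double z, int reach, F f) const {
    int ix = std::min(nx - 1, (int)std::floor((x - ox) / edge));
    int iy = std::min(ny - 1, (int)std::floor((y - oy) / edge));
    int iz = std::min(nz - 1, (int)std::floor((z - oz) / edge));
    for (int a = std::max(0, ix - reach); a <= std::min(nx - 1, ix + reach); ++a)
      for (int b = std::max(0, iy - reach); b <= std::min(ny - 1, iy + reach); ++b)
        for (int c = std::max(0, iz - reach); c <= std::min(nz - 1, iz + reach); ++c)
          for (int j : cells[((size_t)a * ny + b) * nz + c]) f(j);
  }
  bool usable() const {
    return (double)nx * ny * nz < 4e6;
  }
};

inline double d2(const NumericMatrix& A, int i, const NumericMatrix& B, int j) {
  double dx = A(i, 0) - B(j, 0), dy = A(i, 1) - B(j, 1), dz = A(i, 2) - B(j, 2);
  return dx * dx + dy * dy + dz * dz;
}

}  // namespace

// [[Rcpp::export]]
double count_contacts_cpp(NumericMatrix A, NumericMatrix B, double cutoff) {
  const double c2 = cutoff * cutoff;
  double count = 0;
  if (A.nrow() == 0 || B.nrow() == 0) return 0;
  CellGrid grid(B, cutoff);
  if (grid.usable()) {
    for (int i = 0; i < A.nrow(); ++i) {
      grid.neighbors(A(i, 0), A(i, 1), A(i, 2), 1, [&](int j) {
        if (d2(A, i, B, j) <= c2) count += 1;
      });
    }
  } else {
    for (int i = 0; i < A.nrow(); ++i)
      for (int j = 0; j < B.nrow(); ++j)
        if (d2(A, i, B, j) <= c2) count += 1;
  }
  return count;
}

// Shrake-Rupley: per target atom, fraction of sphere points (unit
// directions in `sphere`) at radius r_i + probe not buried inside any
// other context atom's inflated sphere; returns per-target-atom areas.
// `target_idx` are 0-based rows of `coords`; context = all rows.
// [[Rcpp::export]]
NumericVector sasa_cpp(NumericMatrix coords, NumericVector radii,
                       IntegerVector target_idx, double probe,
                       NumericMatrix sphere) {
  const int npts = sphere.nrow();
  double rmax = 0;
  for (int j = 0; j < radii.size(); ++j) rmax = std::max(rmax, radii[j]);
  const double edge = rmax + probe;
  CellGrid grid(coords, edge);
  const bool use_grid = grid.usable();
  NumericVector areas(target_idx.size());

  std::vector<int> nbr;
  for (int t = 0; t < target_idx.size(); ++t) {
    const int i = target_idx[t];
    const double ri = radii[i] + probe;
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    nbr.clear();
    // atom j can bury a point of atom i only if |ci-cj| < ri + rj + probe
    if (use_grid) {
      int reach = (int)std::ceil((ri + rmax + probe) / edge);
      grid.neighbors(xi, yi, zi, reach, [&](int j) {
        if (j == i) return;
        double rj = radii[j] + probe, lim = ri + rj;
        if (d2(coords, i, coords, j) < lim * lim) nbr.push_back(j);
      });
    } else {
      for (int j = 0; j < coords.nrow(); ++j) {
        if (j == i) continue;
        double rj = radii[j] + probe, lim = ri + rj;
        if (d2(coords, i, coords, j) < lim * lim) nbr.push_back(j);
      }
    }
    int acc = 0;
    for (int p = 0; p < npts; ++p) {
      const double px = xi + ri * sphere(p, 0);
      const double py = yi + ri * sphere(p, 1);
      const double pz = zi + ri * sphere(p, 2);
      bool buried = false;
      for (int j : nbr) {
        const double rj = radii[j] + probe;
        const double dx = px - coords(j, 0), dy = py - coords(j, 1),
                     dz = pz - coords(j, 2);
        // boundary (with a hair of slack for round-off) counts as buried
        // so that a coincident duplicate of an atom occludes it completely
        if (dx * dx + dy * dy + dz * dz <= rj * rj * (1.0 + 1e-10)) {
          buried = true; break;
        }
      }
      if (!buried) ++acc;
    }
    areas[t] = 4.0 * M_PI * ri * ri * (double)acc / npts;
  }
  return areas;
}
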