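#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Planar force relaxation for one insertion generation.
//
// Forces act in the x-z plane only (the vertical axis is fixed per depth
// stratum): a spring pulls each node toward its parent's planar position,
// and active non-pinned nodes repel each other with an inverse-square force
// cut off at `cutoff`.  Neighbor search uses a uniform grid with cell size
// `cutoff`; traversal is in node-index order with a fixed cell visiting
// order, so force accumulation — and therefore the result — is fully
// deterministic.  `temp` scales each node's displacement (cooled earlier
// generations move less).  Returns the relaxed positions, the number of
// iterations used, and a non-finite flag (the caller halves dt and retries).

static inline long long cell_key(int cx, int cz) {
  return (static_cast<long long>(cx) << 32) ^ (static_cast<unsigned int>(cz));
}

// [[Rcpp::export]]
List relax_cpp(NumericMatrix pos, IntegerVector parent, LogicalVector active,
               LogicalVector pinned, NumericVector temp, double spring_k,
               double repulsion_k, double cutoff, double damping, double eps,
               int max_iter, double dt) {
  const int n = pos.nrow();
  std::vector<double> x(n), z(n), vx(n, 0.0), vz(n, 0.0), fx(n), fz(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); z[i] = pos(i, 1); }

  std::vector<int> movable; // active and not pinned
  std::vector<int> act;     // active (spring targets may be pinned)
  movable.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (active[i]) {
      act.push_back(i);
      if (!pinned[i]) movable.push_back(i);
    }
  }

  const double cutoff2 = cutoff * cutoff;
  bool nonfinite = false;
  int iter = 0;

  std::unordered_map<long long, std::vector<int>> grid;
  grid.reserve(movable.size() * 2 + 8);

  for (iter = 0; iter < max_iter; ++iter) {
    for (int i = 0; i < n; ++i) { fx[i] = 0.0; fz[i] = 0.0; }

    // springs toward parents (parent may be pinned or inactive-placed)
    for (size_t a = 0; a < act.size(); ++a) {
      int i = act[a];
      if (pinned[i]) continue;
      int p = parent[i];
      if (p >= 0) {
        fx[i] += spring_k * (x[p] - x[i]);
        fz[i] += spring_k * (z[p] - z[i]);
      }
    }

    // grid over movable nodes
    grid.clear();
    for (size_t a = 0; a < movable.size(); ++a) {
      int i = movable[a];
      int cx = (int)std::floor(x[i] / cutoff);
      int cz = (int)std::floor(z[i] / cutoff);
      grid[cell_key(cx, cz)].push_back(i);
    }

    // pairwise repulsion, each unordered pair once (j > i)
    for (size_t a = 0; a < movable.size(); ++a) {
      int i = movable[a];
      int cx = (int)std::floor(x[i] / cutoff);
      int cz = (int)std::floor(z[i] / cutoff);
      for (int dxc = -1; dxc <= 1; ++dxc) {
        for (int dzc = -1; dzc <= 1; ++dzc) {
          auto it = grid.find(cell_key(cx + dxc, cz + dzc));
          if (it == grid.end()) continue;
          const std::vector<int>& cell = it->second;
          for (size_t b = 0; b < cell.size(); ++b) {
            int j = cell[b];
            if (j <= i) continue;
            double dx = x[i] - x[j];
            double dz = z[i] - z[j];
            double d2 = dx * dx + dz * dz;
            if (d2 > cutoff2) continue;
            if (d2 < 1e-12) { // coincident: deterministic nudge
              dx = 1e-6 * (double)(j - i);
              dz = 0.0;
              d2 = dx * dx;
            }
            double d = std::sqrt(d2);
            double f = repulsion_k / d2; // inverse-square magnitude
            double ux = dx / d, uz = dz / d;
            fx[i] += f * ux; fz[i] += f * uz;
            fx[j] -= f * ux; fz[j] -= f * uz;
          }
        }
      }
    }

    // integrate
    double maxdisp = 0.0;
    for (size_t a = 0; a < movable.size(); ++a) {
      int i = movable[a];
      vx[i] = (vx[i] + fx[i] * dt) * damping;
      vz[i] = (vz[i] + fz[i] * dt) * damping;
      double dxs = vx[i] * dt * temp[i];
      double dzs = vz[i] * dt * temp[i];
      x[i] += dxs;
      z[i] += dzs;
      double m = std::sqrt(dxs * dxs + dzs * dzs);
      if (m > maxdisp) maxdisp = m;
      if (!std::isfinite(x[i]) || !std::isfinite(z[i])) nonfinite = true;
    }
    if (nonfinite) break;
    if (maxdisp < eps) { ++iter; break; }
  }

  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i, 0) = x[i]; out(i, 1) = z[i]; }
  return List::create(_["pos"] = out, _["iterations"] = iter,
                      _["nonfinite"] = nonfinite);
}
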