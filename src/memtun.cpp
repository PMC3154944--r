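#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Grid node linear index: i + nx*(j + ny*k), 0-based.

// Clearance at each grid node: distance to the nearest atom *surface*
// (center distance minus that atom's vdW radius), clipped at 0.
// [[Rcpp::export(name = ".cpp_clearance_field")]]
NumericVector cpp_clearance_field(NumericMatrix coords, NumericVector radii,
                                  NumericVector origin, IntegerVector dims,
                                  double spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int natom = coords.nrow();
  NumericVector out((R_xlen_t)nx * ny * nz);
  // cell list over atoms for locality
  const double cell = 4.0;
  double maxr = 0.0;
  for (int a = 0; a < natom; ++a) maxr = std::max(maxr, radii[a]);
  double x0 = origin[0], y0 = origin[1], z0 = origin[2];
  double xmax = x0 + (nx - 1) * spacing, ymax = y0 + (ny - 1) * spacing,
         zmax = z0 + (nz - 1) * spacing;
  int cnx = (int)((xmax - x0) / cell) + 1, cny = (int)((ymax - y0) / cell) + 1,
      cnz = (int)((zmax - z0) / cell) + 1;
  std::vector<std::vector<int> > cells((size_t)cnx * cny * cnz);
  for (int a = 0; a < natom; ++a) {
    int ci = std::min(cnx - 1, std::max(0, (int)((coords(a, 0) - x0) / cell)));
    int cj = std::min(cny - 1, std::max(0, (int)((coords(a, 1) - y0) / cell)));
    int ck = std::min(cnz - 1, std::max(0, (int)((coords(a, 2) - z0) / cell)));
    cells[ci + (size_t)cnx * (cj + (size_t)cny * ck)].push_back(a);
  }
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    double gz = z0 + k * spacing;
    for (int j = 0; j < ny; ++j) {
      double gy = y0 + j * spacing;
      for (int i = 0; i < nx; ++i, ++idx) {
        double gx = x0 + i * spacing;
        // expanding shell search over cells
        int ci = std::min(cnx - 1, std::max(0, (int)((gx - x0) / cell)));
        int cj = std::min(cny - 1, std::max(0, (int)((gy - y0) / cell)));
        int ck = std::min(cnz - 1, std::max(0, (int)((gz - z0) / cell)));
        double best = R_PosInf;
        int maxring = std::max(cnx, std::max(cny, cnz));
        for (int ring = 0; ring <= maxring; ++ring) {
          // once we have a candidate, stop when further rings cannot improve:
          // nearest possible center distance in ring r is (r-1)*cell
          if (best < R_PosInf && (ring - 1) * cell - maxr > best) break;
          bool any = false;
          for (int dk = -ring; dk <= ring; ++dk) {
            int kk = ck + dk;
            if (kk < 0 || kk >= cnz) continue;
            for (int dj = -ring; dj <= ring; ++dj) {
              int jj = cj + dj;
              if (jj < 0 || jj >= cny) continue;
              for (int di = -ring; di <= ring; ++di) {
                if (std::max(std::abs(di), std::max(std::abs(dj), std::abs(dk))) != ring)
                  continue;
                int ii = ci + di;
                if (ii < 0 || ii >= cnx) continue;
                any = true;
                const std::vector<int>& cv =
                    cells[ii + (size_t)cnx * (jj + (size_t)cny * kk)];
                for (size_t t = 0; t < cv.size(); ++t) {
                  int a = cv[t];
                  double dx = gx - coords(a, 0), dy = gy - coords(a, 1),
                         dz = gz - coords(a, 2);
                  double d = std::sqrt(dx * dx + dy * dy + dz * dz) - radii[a];
                  if (d < best) best = d;
                }
              }
            }
          }
          if (!any && ring > maxring) break;
        }
        out[idx] = best < 0 ? 0.0 : best;
      }
    }
  }
  return out;
}

// Maximin (widest-path) Dijkstra from a start node over the 26-connected
// grid: bottleneck[v] = max over paths P(start->v) of min clearance on P.
// [[Rcpp::export(name = ".cpp_widest_path")]]
List cpp_widest_path(NumericVector clearance, IntegerVector dims, int start) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector bott(n, -1.0);
  IntegerVector parent(n, -1);
  std::priority_queue<std::pair<double, R_xlen_t> > pq;
  bott[start] = clearance[start];
  pq.push(std::make_pair(bott[start], (R_xlen_t)start));
  while (!pq.empty()) {
    double b = pq.top().first;
    R_xlen_t v = pq.top().second;
    pq.pop();
    if (b < bott[v]) continue;
    int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / ((R_xlen_t)nx * ny));
    for (int dk = -1; dk <= 1; ++dk) {
      int kk = k + dk;
      if (kk < 0 || kk >= nz) continue;
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = j + dj;
        if (jj < 0 || jj >= ny) continue;
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          int ii = i + di;
          if (ii < 0 || ii >= nx) continue;
          R_xlen_t u = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
          double nb = std::min(b, clearance[u]);
          if (nb > bott[u]) {
            bott[u] = nb;
            parent[u] = (int)v;
            pq.push(std::make_pair(nb, u));
          }
        }
      }
    }
  }
  return List::create(Named("bottleneck") = bott, Named("parent") = parent);
}

// Per-residue minimum heavy-atom distance to a set of points.
// resindex: 1-based residue group index per protein atom.
// [[Rcpp::export(name = ".cpp_min_dist_by_group")]]
NumericVector cpp_min_dist_by_group(NumericMatrix prot, IntegerVector resindex,
                                    int ngroup, NumericMatrix lip) {
  NumericVector out(ngroup, R_PosInf);
  const int np = prot.nrow(), nl = lip.nrow();
  for (int i = 0; i < np; ++i) {
    double best = R_PosInf;
    double px = prot(i, 0), py = prot(i, 1), pz = prot(i, 2);
    for (int j = 0; j < nl; ++j) {
      double dx = px - lip(j, 0), dy = py - lip(j, 1), dz = pz - lip(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    int g = resindex[i] - 1;
    double d = std::sqrt(best);
    if (d < out[g]) out[g] = d;
  }
  return out;
}
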