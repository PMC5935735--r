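#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <numeric>
#include <functional>

using namespace Rcpp;

// Node indexing: idx = i + nx*(j + ny*k), 0-based, x fastest (R column-major
// order for array(dim = c(nx, ny, nz))).

static inline int node(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + (size_t)ny * k);
}

// Solute mask on grid nodes. With do_erode = false this marks every node
// within (radius_i + inflate) of an atom centre (used for the ion-exclusion
// region). With do_erode = true it builds the molecular (solvent-excluded)
// surface region: inflate all atom spheres by the probe radius, then erode
// by the probe radius from the solvent side, which keeps probe-inaccessible
// re-entrant necks inside the solute.
// [[Rcpp::export]]
LogicalVector cpp_solute_mask(NumericMatrix xyz, NumericVector radius,
                              NumericVector origin, double h,
                              IntegerVector dims, double inflate,
                              bool do_erode) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t ntot = (size_t)nx * ny * nz;
  std::vector<char> grown(ntot, 0);
  const int nat = xyz.nrow();

  for (int a = 0; a < nat; ++a) {
    const double R = radius[a] + inflate;
    if (R <= 0) continue;
    const double cx = xyz(a, 0), cy = xyz(a, 1), cz = xyz(a, 2);
    const int i0 = std::max(0, (int)std::ceil((cx - R - origin[0]) / h));
    const int i1 = std::min(nx - 1, (int)std::floor((cx + R - origin[0]) / h));
    const int j0 = std::max(0, (int)std::ceil((cy - R - origin[1]) / h));
    const int j1 = std::min(ny - 1, (int)std::floor((cy + R - origin[1]) / h));
    const int k0 = std::max(0, (int)std::ceil((cz - R - origin[2]) / h));
    const int k1 = std::min(nz - 1, (int)std::floor((cz + R - origin[2]) / h));
    const double R2 = R * R;
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + k * h - cz;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + j * h - cy;
        const double d2yz = dy * dy + dz * dz;
        if (d2yz > R2) continue;
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + i * h - cx;
          if (dx * dx + d2yz <= R2) grown[node(i, j, k, nx, ny)] = 1;
        }
      }
    }
  }

  if (!do_erode || nat == 0) {
    LogicalVector out(ntot);
    for (size_t t = 0; t < ntot; ++t) out[t] = grown[t] != 0;
    return out;
  }

  // Erode: a grown node is outside the molecular surface if some probe
  // sphere position entirely outside the inflated atom spheres reaches it.
  // Candidate probe centres are found by projecting each solvent node that
  // touches the grown region onto the nearest inflated sphere (a continuous
  // position, so the erosion front is not quantized to the lattice); where
  // the projection lands inside another inflated sphere (a concave seam)
  // the lattice node itself is used. Assumes the grid pads the solute by
  // more than the probe radius, so the outer faces never clip the surface.
  std::vector<char> keep(grown);
  const double P = inflate, P2 = P * P;
  const int rr = (int)std::ceil(P / h) + 1;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const size_t t = node(i, j, k, nx, ny);
        if (grown[t]) continue;
        bool boundary =
          (i > 0      && grown[node(i - 1, j, k, nx, ny)]) ||
          (i < nx - 1 && grown[node(i + 1, j, k, nx, ny)]) ||
          (j > 0      && grown[node(i, j - 1, k, nx, ny)]) ||
          (j < ny - 1 && grown[node(i, j + 1, k, nx, ny)]) ||
          (k > 0      && grown[node(i, j, k - 1, nx, ny)]) ||
          (k < nz - 1 && grown[node(i, j, k + 1, nx, ny)]);
        if (!boundary) continue;
        double q[3] = { origin[0] + i * h, origin[1] + j * h, origin[2] + k * h };
        // project onto the nearest inflated sphere
        int best = -1; double bestgap = R_PosInf;
        for (int a = 0; a < nat; ++a) {
          const double dx = q[0] - xyz(a, 0), dy = q[1] - xyz(a, 1),
                       dz = q[2] - xyz(a, 2);
          const double gap = std::sqrt(dx * dx + dy * dy + dz * dz)
            - (radius[a] + inflate);
          if (gap < bestgap) { bestgap = gap; best = a; }
        }
        if (best >= 0 && bestgap > 0) {
          const double Ra = radius[best] + inflate;
          double v[3] = { q[0] - xyz(best, 0), q[1] - xyz(best, 1),
                          q[2] - xyz(best, 2) };
          const double nv = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
          double proj[3] = { xyz(best, 0) + v[0] * Ra / nv,
                             xyz(best, 1) + v[1] * Ra / nv,
                             xyz(best, 2) + v[2] * Ra / nv };
          bool valid = true;
          for (int a = 0; a < nat && valid; ++a) {
            if (a == best) continue;
            const double dx = proj[0] - xyz(a, 0), dy = proj[1] - xyz(a, 1),
                         dz = proj[2] - xyz(a, 2);
            const double Rb = radius[a] + inflate;
            if (dx * dx + dy * dy + dz * dz < Rb * Rb - 1e-12) valid = false;
          }
          if (valid) { q[0] = proj[0]; q[1] = proj[1]; q[2] = proj[2]; }
        }
        const int ci = (int)std::round((q[0] - origin[0]) / h);
        const int cj = (int)std::round((q[1] - origin[1]) / h);
        const int ck = (int)std::round((q[2] - origin[2]) / h);
        const int ia = std::max(0, ci - rr), ib = std::min(nx - 1, ci + rr);
        const int ja = std::max(0, cj - rr), jb = std::min(ny - 1, cj + rr);
        const int ka = std::max(0, ck - rr), kb = std::min(nz - 1, ck + rr);
        for (int kk = ka; kk <= kb; ++kk) {
          const double dz = origin[2] + kk * h - q[2];
          for (int jj = ja; jj <= jb; ++jj) {
            const double dy = origin[1] + jj * h - q[1];
            const double d2 = dy * dy + dz * dz;
            if (d2 > P2) continue;
            for (int ii = ia; ii <= ib; ++ii) {
              const double dx = origin[0] + ii * h - q[0];
              if (dx * dx + d2 <= P2) keep[node(ii, jj, kk, nx, ny)] = 0;
            }
          }
        }
      }
    }
  }
  LogicalVector out(ntot);
  for (size_t t = 0; t < ntot; ++t) out[t] = keep[t] != 0;
  return out;
}

// Red-black successive over-relaxation for the discretized linearized
// Poisson-Boltzmann operator
//   sum_edges eps_edge (phi_nbr - phi_0) - kappa2 h^2 phi_0 + src_0 = 0
// with src_0 = 4 pi C q_0 / h (C the electrostatic constant) and Dirichlet
// values preloaded on the outer faces of `phi`. Returns phi, the iteration
// count and the final residual (max Gauss-Seidel displacement, potential
// units).
// [[Rcpp::export]]
List cpp_sor_lpb(NumericVector phi0, NumericVector epsx, NumericVector epsy,
                 NumericVector epsz, NumericVector kap2h2, NumericVector src,
                 IntegerVector dims, double omega, double tol, int max_iter) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector phi = clone(phi0);
  double *p = REAL(phi);
  const double *ex = REAL(epsx), *ey = REAL(epsy), *ez = REAL(epsz);
  const double *kp = REAL(kap2h2), *s = REAL(src);

  const int nxe = nx - 1, nye = ny - 1;
  double resid = R_PosInf;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    resid = 0.0;
    for (int colour = 0; colour < 2; ++colour) {
      for (int k = 1; k < nz - 1; ++k) {
        for (int j = 1; j < ny - 1; ++j) {
          // choose i parity so (i + j + k) % 2 == colour
          int istart = 1;
          if (((istart + j + k) & 1) != colour) ++istart;
          for (int i = istart; i < nx - 1; i += 2) {
            const size_t t = node(i, j, k, nx, ny);
            const double exm = ex[(i - 1) + nxe * (j + (size_t)ny * k)];
            const double exp_ = ex[i + nxe * (j + (size_t)ny * k)];
            const double eym = ey[i + nx * ((j - 1) + (size_t)nye * k)];
            const double eyp = ey[i + nx * (j + (size_t)nye * k)];
            const double ezm = ez[i + nx * (j + (size_t)ny * (k - 1))];
            const double ezp = ez[i + nx * (j + (size_t)ny * k)];
            const double diag = exm + exp_ + eym + eyp + ezm + ezp + kp[t];
            const double rhs = exm * p[t - 1] + exp_ * p[t + 1]
              + eym * p[t - nx] + eyp * p[t + nx]
              + ezm * p[t - (size_t)nx * ny] + ezp * p[t + (size_t)nx * ny]
              + s[t];
            const double gs = rhs / diag;
            const double d = gs - p[t];
            if (std::fabs(d) > resid) resid = std::fabs(d);
            p[t] += omega * d;
          }
        }
      }
    }
    if (resid <= tol) break;
  }
  return List::create(_["phi"] = phi, _["iterations"] = std::min(it, max_iter),
                      _["residual"] = resid, _["converged"] = resid <= tol);
}

// Minimax connection level between two cells of a 2-D energy grid: the
// smallest energy E* such that start and end are connected through cells
// with energy <= E* (4-connectivity). Union-find over cells visited in
// order of increasing energy. Serves as a brute-force saddle-energy oracle
// for chain-of-states optimizers.
// [[Rcpp::export]]
double cpp_grid_minimax(NumericMatrix energy, int i0, int j0, int i1, int j1) {
  const int nr = energy.nrow(), nc = energy.ncol();
  const size_t n = (size_t)nr * nc;
  std::vector<int> parent(n);
  std::iota(parent.begin(), parent.end(), 0);
  std::vector<char> active(n, 0);

  std::vector<int> order(n);
  std::iota(order.begin(), order.end(), 0);
  const double *e = REAL(energy);
  std::sort(order.begin(), order.end(),
            [e](int a, int b) { return e[a] < e[b]; });

  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };

  const int a = i0 + nr * j0, b = i1 + nr * j1;
  for (size_t t = 0; t < n; ++t) {
    const int c = order[t];
    active[c] = 1;
    const int i = c % nr, j = c / nr;
    const int nbr[4] = { i > 0 ? c - 1 : -1, i < nr - 1 ? c + 1 : -1,
                         j > 0 ? c - nr : -1, j < nc - 1 ? c + nr : -1 };
    for (int q = 0; q < 4; ++q) {
      if (nbr[q] >= 0 && active[nbr[q]]) {
        parent[find(c)] = find(nbr[q]);
      }
    }
    if (active[a] && active[b] && find(a) == find(b)) {
      return e[c];
    }
  }
  return R_PosInf;
}

// Fraction of each mixed (inside/outside) grid edge lying inside the union
// of atom spheres, by exact segment-sphere intersection. Used to place the
// dielectric interface with sub-grid resolution: the edge dielectric is the
// length-weighted harmonic mean 1 / (f/eps_in + (1-f)/eps_out). Edges in
// purely re-entrant boundary regions (no sphere crosses them) fall back to
// f = 1/2. Non-mixed edges are returned as f = 1 (inside) or 0 (outside).
// `axis` is 0, 1 or 2.
// [[Rcpp::export]]
NumericVector cpp_edge_fractions(NumericMatrix xyz, NumericVector radius,
                                 NumericVector origin, double h,
                                 IntegerVector dims, LogicalVector inside,
                                 int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  int ex = nx, ey = ny, ez = nz;
  if (axis == 0) ex = nx - 1; else if (axis == 1) ey = ny - 1; else ez = nz - 1;
  const size_t nedge = (size_t)ex * ey * ez;
  NumericVector out(nedge);
  const int nat = xyz.nrow();

  for (int k = 0; k < ez; ++k) {
    for (int j = 0; j < ey; ++j) {
      for (int i = 0; i < ex; ++i) {
        const size_t t = i + (size_t)ex * (j + (size_t)ey * k);
        int i2 = i + (axis == 0), j2 = j + (axis == 1), k2 = k + (axis == 2);
        const bool m0 = inside[node(i, j, k, nx, ny)];
        const bool m1 = inside[node(i2, j2, k2, nx, ny)];
        if (m0 == m1) { out[t] = m0 ? 1.0 : 0.0; continue; }
        // mixed edge: accumulate the in-sphere portion of the segment
        double p0[3] = { origin[0] + i * h, origin[1] + j * h, origin[2] + k * h };
        double u[3] = { 0, 0, 0 };
        u[axis] = h;
        // merge intervals on the fly: collect then sort
        std::vector<std::pair<double,double>> iv;
        for (int a = 0; a < nat; ++a) {
          const double dx = p0[0] - xyz(a, 0), dy = p0[1] - xyz(a, 1),
                       dz = p0[2] - xyz(a, 2);
          const double b = (dx * u[0] + dy * u[1] + dz * u[2]);
          const double c = dx * dx + dy * dy + dz * dz - radius[a] * radius[a];
          const double A = h * h;
          const double disc = b * b - A * c;
          if (disc <= 0) continue;
          const double sq = std::sqrt(disc);
          double t0 = (-b - sq) / A, t1 = (-b + sq) / A;
          t0 = std::max(t0, 0.0); t1 = std::min(t1, 1.0);
          if (t1 > t0) iv.emplace_back(t0, t1);
        }
        double f;
        if (iv.empty()) {
          f = 0.5;  // re-entrant surface crossing, position unknown
        } else {
          std::sort(iv.begin(), iv.end());
          double tot = 0, cur0 = iv[0].first, cur1 = iv[0].second;
          for (size_t q = 1; q < iv.size(); ++q) {
            if (iv[q].first > cur1) { tot += cur1 - cur0; cur0 = iv[q].first; cur1 = iv[q].second; }
            else cur1 = std::max(cur1, iv[q].second);
          }
          tot += cur1 - cur0;
          f = std::min(std::max(tot, 0.0), 1.0);
          if (f <= 0) f = 0.5;
        }
        out[t] = f;
      }
    }
  }
  return out;
}
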