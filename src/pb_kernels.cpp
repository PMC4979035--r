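#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Node-centred finite-difference grid. Linear index idx = i + nx*(j + ny*k),
// node position = origin + (i,j,k)*h. Face dielectric arrays epsx/epsy/epsz
// hold the value on the face between node (i,j,k) and its +x/+y/+z
// neighbour (the last slab in each direction is unused).

static inline double minSurfDist(double px, double py, double pz,
                                 const NumericMatrix &coords,
                                 const NumericVector &radii) {
  double best = 1e30;
  const int n = coords.nrow();
  for (int a = 0; a < n; ++a) {
    const double dx = px - coords(a, 0), dy = py - coords(a, 1),
                 dz = pz - coords(a, 2);
    const double d = std::sqrt(dx * dx + dy * dy + dz * dz) - radii[a];
    if (d < best) best = d;
  }
  return best;
}

// Solvent-excluded-surface test by inflate/deflate: a point is interior if
// it lies inside some atom sphere, or inside the probe-inflated region and
// no solvent-accessible-exterior lattice node sits within one probe radius
// (probe rolling approximated on the grid lattice).
// [[Rcpp::export]]
List cpp_dielectric_faces(NumericMatrix coords, NumericVector radii,
                          NumericVector origin, double h, IntegerVector dims,
                          double probe, double eps_in, double eps_out) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;

  // node-level solvent-accessible mask (true = inside inflated region)
  std::vector<char> sas(ntot);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const double px = origin[0] + i * h, py = origin[1] + j * h,
                     pz = origin[2] + k * h;
        sas[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] =
            minSurfDist(px, py, pz, coords, radii) <= probe;
      }

  // lattice offsets within one probe radius
  const int m = (int)std::ceil(probe / h);
  std::vector<int> offs;
  for (int dk = -m; dk <= m; ++dk)
    for (int dj = -m; dj <= m; ++dj)
      for (int di = -m; di <= m; ++di) {
        if (h * std::sqrt((double)(di * di + dj * dj + dk * dk)) <= probe) {
          offs.push_back(di); offs.push_back(dj); offs.push_back(dk);
        }
      }
  const int noff = (int)offs.size() / 3;

  // interior test for an arbitrary point (face midpoints live off-lattice)
  auto interior = [&](double px, double py, double pz) -> bool {
    const double d = minSurfDist(px, py, pz, coords, radii);
    if (d > probe) return false;   // outside inflated region
    if (d <= 0.0) return true;     // inside a van der Waals sphere
    // probe-shell point: eroded if a solvent-exterior node is within probe
    const int i0 = (int)std::lround((px - origin[0]) / h);
    const int j0 = (int)std::lround((py - origin[1]) / h);
    const int k0 = (int)std::lround((pz - origin[2]) / h);
    for (int t = 0; t < noff; ++t) {
      const int i = i0 + offs[3 * t], j = j0 + offs[3 * t + 1],
                k = k0 + offs[3 * t + 2];
      if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz)
        return false;  // beyond the box counts as solvent
      if (!sas[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)]) return false;
    }
    return true;
  };

  NumericVector epsx(ntot, eps_out), epsy(ntot, eps_out), epsz(ntot, eps_out);
  LogicalVector inside(ntot);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t id = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        const double px = origin[0] + i * h, py = origin[1] + j * h,
                     pz = origin[2] + k * h;
        inside[id] = interior(px, py, pz);
        if (i + 1 < nx && interior(px + 0.5 * h, py, pz)) epsx[id] = eps_in;
        if (j + 1 < ny && interior(px, py + 0.5 * h, pz)) epsy[id] = eps_in;
        if (k + 1 < nz && interior(px, py, pz + 0.5 * h)) epsz[id] = eps_in;
      }
  return List::create(_["epsx"] = epsx, _["epsy"] = epsy, _["epsz"] = epsz,
                      _["inside"] = inside);
}

// Red-black successive over-relaxation for sum_f eps_f (phi_nb - phi_c) =
// -src_c (src = 4*pi*k_coulomb*q/h). Dirichlet boundary: phi fixed on the
// box faces. Returns iterations used and final relative residual.
// [[Rcpp::export]]
List cpp_sor_solve(NumericVector phi, NumericVector epsx, NumericVector epsy,
                   NumericVector epsz, NumericVector src, IntegerVector dims,
                   int maxit, double tol, double omega) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  double *p = REAL(phi);
  const double *ex = REAL(epsx), *ey = REAL(epsy), *ez = REAL(epsz),
               *s = REAL(src);
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  double srcNorm = 0.0;
  for (R_xlen_t t = 0; t < src.size(); ++t) srcNorm += s[t] * s[t];
  srcNorm = std::sqrt(srcNorm);
  if (srcNorm == 0.0) srcNorm = 1.0;

  double resid = 1e30;
  int it = 0;
  for (it = 1; it <= maxit; ++it) {
    for (int colour = 0; colour < 2; ++colour) {
      for (int k = 1; k < nz - 1; ++k)
        for (int j = 1; j < ny - 1; ++j) {
          int i0 = 1 + ((j + k + colour) & 1);
          R_xlen_t id = i0 + sy * j + sz * k;
          for (int i = i0; i < nx - 1; i += 2, id += 2) {
            const double exm = ex[id - sx], exp_ = ex[id];
            const double eym = ey[id - sy], eyp = ey[id];
            const double ezm = ez[id - sz], ezp = ez[id];
            const double diag = exm + exp_ + eym + eyp + ezm + ezp;
            const double nb = exm * p[id - sx] + exp_ * p[id + sx] +
                              eym * p[id - sy] + eyp * p[id + sy] +
                              ezm * p[id - sz] + ezp * p[id + sz];
            const double phiNew = (nb + s[id]) / diag;
            p[id] += omega * (phiNew - p[id]);
          }
        }
    }
    if (it % 10 == 0 || it == maxit) {
      double rn = 0.0;
      for (int k = 1; k < nz - 1; ++k)
        for (int j = 1; j < ny - 1; ++j) {
          R_xlen_t id = 1 + sy * j + sz * k;
          for (int i = 1; i < nx - 1; ++i, ++id) {
            const double exm = ex[id - sx], exp_ = ex[id];
            const double eym = ey[id - sy], eyp = ey[id];
            const double ezm = ez[id - sz], ezp = ez[id];
            const double diag = exm + exp_ + eym + eyp + ezm + ezp;
            const double r = exm * p[id - sx] + exp_ * p[id + sx] +
                             eym * p[id - sy] + eyp * p[id + sy] +
                             ezm * p[id - sz] + ezp * p[id + sz] -
                             diag * p[id] + s[id];
            rn += r * r;
          }
        }
      resid = std::sqrt(rn) / srcNorm;
      if (resid < tol) break;
    }
  }
  return List::create(_["iterations"] = it, _["residual"] = resid);
}
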