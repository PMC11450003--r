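#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 2D scalar-acoustic FDTD on a staggered grid, leapfrog in time.
//
// Layout (column-major, z down rows, x across columns):
//   p  : nz x nx        cell-centred pressure, cell (i,j) at z = i*dx, x = j*dx
//   vz : (nz+1) x nx    z particle velocity on horizontal faces; face k sits
//                       between cells k-1 and k, i.e. at z = (k - 0.5)*dx
//   vx : nz x (nx+1)    x particle velocity on vertical faces
//
// Soft (pressure-release) surfaces are the Dirichlet rows i = 0 and i = nz-1
// (p forced to 0 every step).  Lateral edges are rigid faces wrapped in an
// absorbing sponge: fields in the outer `sponge_cells` columns are damped by
// a smooth cubic ramp each step.
//
// The LDV observable is vz on face row 1 (half a cell inside the soft
// detection surface); it is recorded every step at the requested columns.
//
// Time-reversal sources are Dirichlet pressure values imposed at given cells
// (one per source trace) after each pressure update.
//
// Returns the recorded surface velocity, the final pressure field, optional
// snapshots, and a stability flag (max |p| monitored against blow-up).

// [[Rcpp::export]]
List fdtd_core(NumericMatrix c_map, NumericMatrix rho_map,
               double dx, double dt, int nsteps,
               NumericMatrix p0,
               IntegerVector sensor_j,      // 0-based columns for surface vz
               NumericMatrix src_traces,    // nsteps x nsrc (or 0 x 0)
               IntegerVector src_i, IntegerVector src_j,  // 0-based cells
               IntegerVector snap_steps,    // 1-based step indices, sorted
               int sponge_cells, double sponge_strength,
               bool soft_top, bool soft_bottom,
               double blowup_factor) {
  const int nz = c_map.nrow(), nx = c_map.ncol();
  const int nsens = sensor_j.size();
  const int nsrc = src_i.size();
  const int nsnap = snap_steps.size();

  NumericMatrix p(nz, nx), vz(nz + 1, nx), vx(nz, nx + 1);
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < nz; ++i) p(i, j) = p0(i, j);
  if (soft_top)    for (int j = 0; j < nx; ++j) p(0, j) = 0.0;
  if (soft_bottom) for (int j = 0; j < nx; ++j) p(nz - 1, j) = 0.0;

  // precompute update coefficients
  NumericMatrix kap(nz, nx);            // rho * c^2 * dt / dx
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < nz; ++i)
      kap(i, j) = rho_map(i, j) * c_map(i, j) * c_map(i, j) * dt / dx;

  // lateral sponge profile per column (applied to p, vx, vz)
  std::vector<double> w(nx + 1, 1.0);
  if (sponge_cells > 0) {
    for (int j = 0; j <= nx; ++j) {
      double d = 0.0;
      if (j < sponge_cells) d = double(sponge_cells - j) / sponge_cells;
      int jr = (j < nx) ? j : nx - 1;
      if (jr >= nx - sponge_cells)
        d = double(jr - (nx - 1 - sponge_cells)) / sponge_cells;
      w[j] = std::exp(-sponge_strength * d * d * d);
    }
  }

  NumericMatrix u_rec(nsteps, nsens);
  List snapshots(nsnap);
  double p0max = 0.0;
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < nz; ++i) p0max = std::max(p0max, std::fabs(p(i, j)));
  double src_max = 0.0;
  if (nsrc > 0)
    for (int s = 0; s < nsrc; ++s)
      for (int n = 0; n < src_traces.nrow(); ++n)
        src_max = std::max(src_max, std::fabs(src_traces(n, s)));
  const double ref_amp = std::max(p0max, src_max);
  bool stable = true;
  double max_abs_p = p0max;
  int isnap = 0;

  for (int n = 0; n < nsteps && stable; ++n) {
    // velocity updates (interior faces only; edge faces stay rigid)
    for (int j = 0; j < nx; ++j) {
      double* pj = &p(0, j);
      double* vzj = &vz(0, j);
      const double* rj = &rho_map(0, j);
      for (int k = 1; k < nz; ++k) {
        double rho_f = 0.5 * (rj[k - 1] + rj[k]);
        vzj[k] -= dt / (rho_f * dx) * (pj[k] - pj[k - 1]);
      }
    }
    for (int j = 1; j < nx; ++j) {
      double* pj = &p(0, j);
      double* pjm = &p(0, j - 1);
      double* vxj = &vx(0, j);
      const double* rj = &rho_map(0, j);
      const double* rjm = &rho_map(0, j - 1);
      for (int i = 0; i < nz; ++i) {
        double rho_f = 0.5 * (rjm[i] + rj[i]);
        vxj[i] -= dt / (rho_f * dx) * (pj[i] - pjm[i]);
      }
    }

    // pressure update
    for (int j = 0; j < nx; ++j) {
      double* pj = &p(0, j);
      const double* kj = &kap(0, j);
      const double* vzj = &vz(0, j);
      const double* vxj = &vx(0, j);
      const double* vxj1 = &vx(0, j + 1);
      for (int i = 0; i < nz; ++i)
        pj[i] -= kj[i] * (vzj[i + 1] - vzj[i] + vxj1[i] - vxj[i]);
    }
    if (soft_top)    for (int j = 0; j < nx; ++j) p(0, j) = 0.0;
    if (soft_bottom) for (int j = 0; j < nx; ++j) p(nz - 1, j) = 0.0;

    // Dirichlet pressure sources (time reversal)
    for (int s = 0; s < nsrc; ++s)
      p(src_i[s], src_j[s]) = src_traces(n, s);

    // lateral sponge
    if (sponge_cells > 0) {
      for (int j = 0; j < nx; ++j) {
        if (w[j] == 1.0) continue;
        double wj = w[j];
        double* pj = &p(0, j);
        double* vzj = &vz(0, j);
        for (int i = 0; i < nz; ++i) pj[i] *= wj;
        for (int k = 0; k <= nz; ++k) vzj[k] *= wj;
      }
      for (int j = 0; j <= nx; ++j) {
        if (w[j] == 1.0) continue;
        double wj = w[j];
        double* vxj = &vx(0, j);
        for (int i = 0; i < nz; ++i) vxj[i] *= wj;
      }
    }

    // record surface velocity (face row 1: half a cell below z = 0)
    for (int s = 0; s < nsens; ++s) u_rec(n, s) = vz(1, sensor_j[s]);

    // stability monitor
    double mx = 0.0;
    for (int j = 0; j < nx; ++j) {
      const double* pj = &p(0, j);
      for (int i = 0; i < nz; ++i) {
        double a = std::fabs(pj[i]);
        if (a > mx) mx = a;
      }
    }
    if (!std::isfinite(mx) || (ref_amp > 0 && mx > blowup_factor * ref_amp))
      stable = false;
    if (mx > max_abs_p) max_abs_p = mx;

    while (isnap < nsnap && snap_steps[isnap] == n + 1) {
      snapshots[isnap] = clone(p);
      ++isnap;
    }
  }

  return List::create(_["u"] = u_rec, _["p_final"] = p,
                      _["snapshots"] = snapshots,
                      _["max_abs_p"] = max_abs_p,
                      _["stable"] = stable);
}
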