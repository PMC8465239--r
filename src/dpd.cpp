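// DPD engine: soft conservative pair forces, pairwise dissipative/random
// thermostat, harmonic bonds, angle bending, cell-list neighbour search,
// modified velocity-Verlet, and Muller-Plathe momentum swaps.
// Reduced units throughout: lengths in rc, energies in kBT, masses in m,
// time in tau = rc*sqrt(m/kBT). Bead mass is 1.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-based random stream: zeta_ij for a pair is a pure function of
// (seed, step, i, j) with i < j, so zeta_ij == zeta_ji holds by construction
// and the result is independent of pair iteration order.
// ---------------------------------------------------------------------------
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline double u01(uint64_t h) {
  // 53-bit mantissa uniform in [0, 1)
  return (double)(h >> 11) * (1.0 / 9007199254740992.0);
}

static inline double zeta_pair(uint64_t seed, uint64_t step,
                               uint32_t i, uint32_t j, bool gaussian) {
  uint64_t h = splitmix64(seed ^ splitmix64(step + 0x51ED270B2F2C9E8BULL));
  h = splitmix64(h ^ (((uint64_t)i << 32) | (uint64_t)j));
  if (!gaussian) {
    // uniform with zero mean, unit variance: width sqrt(12)
    return (u01(h) - 0.5) * 3.4641016151377544;
  }
  double u1 = u01(h);
  double u2 = u01(splitmix64(h ^ 0xA3EC647659359ACDULL));
  if (u1 < 1e-300) u1 = 1e-300;
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
}

// ---------------------------------------------------------------------------
// geometry helpers
// ---------------------------------------------------------------------------
static inline double wrap0L(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x = 0.0; // guard against floor rounding at the upper edge
  return x;
}

static inline void min_image(double* d, const double* L) {
  for (int k = 0; k < 3; ++k) d[k] -= L[k] * std::nearbyint(d[k] / L[k]);
}

// ---------------------------------------------------------------------------
// pair iteration: cell list when every axis holds >= 3 cells of edge >= rc,
// otherwise O(N^2) with minimum image. The callback receives (i, j, d[3], r)
// with d = r_i - r_j (minimum image), r = |d| < rc.
// ---------------------------------------------------------------------------
template <typename F>
static void for_each_pair(int N, const std::vector<double>& x,
                          const double* L, double rc, F&& fn) {
  int m[3];
  bool cells_ok = true;
  for (int k = 0; k < 3; ++k) {
    m[k] = (int)std::floor(L[k] / rc);
    if (m[k] < 3) cells_ok = false;
  }
  const double rc2 = rc * rc;
  if (!cells_ok) {
    for (int i = 0; i < N; ++i) {
      for (int j = i + 1; j < N; ++j) {
        double d[3] = { x[3*i] - x[3*j], x[3*i+1] - x[3*j+1], x[3*i+2] - x[3*j+2] };
        min_image(d, L);
        double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
        if (r2 < rc2 && r2 > 0.0) fn(i, j, d, std::sqrt(r2));
      }
    }
    return;
  }
  int ncell = m[0] * m[1] * m[2];
  std::vector<int> head(ncell, -1), nxt(N, -1);
  double inv[3] = { m[0] / L[0], m[1] / L[1], m[2] / L[2] };
  auto cidx = [&](int cx, int cy, int cz) { return (cz * m[1] + cy) * m[0] + cx; };
  for (int i = 0; i < N; ++i) {
    int cx = (int)(x[3*i]   * inv[0]); if (cx >= m[0]) cx = m[0]-1; if (cx < 0) cx = 0;
    int cy = (int)(x[3*i+1] * inv[1]); if (cy >= m[1]) cy = m[1]-1; if (cy < 0) cy = 0;
    int cz = (int)(x[3*i+2] * inv[2]); if (cz >= m[2]) cz = m[2]-1; if (cz < 0) cz = 0;
    int c = cidx(cx, cy, cz);
    nxt[i] = head[c]; head[c] = i;
  }
  // half-shell of 13 forward neighbours + self
  static const int off[14][3] = {
    {0,0,0}, {1,0,0}, {-1,1,0}, {0,1,0}, {1,1,0},
    {-1,-1,1}, {0,-1,1}, {1,-1,1}, {-1,0,1}, {0,0,1},
    {1,0,1}, {-1,1,1}, {0,1,1}, {1,1,1}
  };
  for (int cz = 0; cz < m[2]; ++cz)
  for (int cy = 0; cy < m[1]; ++cy)
  for (int cx = 0; cx < m[0]; ++cx) {
    int c = cidx(cx, cy, cz);
    for (int o = 0; o < 14; ++o) {
      int nx = (cx + off[o][0] + m[0]) % m[0];
      int ny = (cy + off[o][1] + m[1]) % m[1];
      int nz = (cz + off[o][2] + m[2]) % m[2];
      int c2 = cidx(nx, ny, nz);
      bool same = (o == 0);
      for (int i = head[c]; i >= 0; i = nxt[i]) {
        for (int j = same ? nxt[i] : head[c2]; j >= 0; j = nxt[j]) {
          double d[3] = { x[3*i] - x[3*j], x[3*i+1] - x[3*j+1], x[3*i+2] - x[3*j+2] };
          min_image(d, L);
          double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
          if (r2 < rc2 && r2 > 0.0) fn(i, j, d, std::sqrt(r2));
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// angle force for triple (i, j, k), vertex j; U = kt * (theta - t0)^2.
// Returns forces on i and k (force on j is minus their sum) and the energy.
// ---------------------------------------------------------------------------
static inline double angle_force(const double* u, const double* v,
                                 double kt, double t0,
                                 double* fi, double* fk) {
  double nu = std::sqrt(u[0]*u[0] + u[1]*u[1] + u[2]*u[2]);
  double nv = std::sqrt(v[0]*v[0] + v[1]*v[1] + v[2]*v[2]);
  double c = (u[0]*v[0] + u[1]*v[1] + u[2]*v[2]) / (nu * nv);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  double th = std::acos(c);
  double s = std::sqrt(1.0 - c * c);
  if (s < 1e-8) s = 1e-8; // guarded gradient at theta = 0 or pi
  double dUdth = 2.0 * kt * (th - t0);
  double pref = dUdth / s;
  for (int d = 0; d < 3; ++d) {
    fi[d] = pref * (v[d] / (nu * nv) - c * u[d] / (nu * nu));
    fk[d] = pref * (u[d] / (nu * nv) - c * v[d] / (nv * nv));
  }
  return kt * (th - t0) * (th - t0);
}

// ---------------------------------------------------------------------------
// full force evaluation; fills f (3N) and energies[3] = {pair, bond, angle}
// ---------------------------------------------------------------------------
static void compute_forces(int N, const std::vector<double>& x,
                           const std::vector<double>& v,
                           const std::vector<int>& sp, const double* L,
                           const NumericMatrix& atab, double rc,
                           double gamma, double sigma, double inv_sqrt_dt,
                           uint64_t seed, uint64_t step, bool gaussian,
                           const IntegerMatrix& bonds,
                           const NumericVector& bks, const NumericVector& brs,
                           const IntegerMatrix& angles,
                           const NumericVector& akt, const NumericVector& at0,
                           std::vector<double>& f, double* energies) {
  std::fill(f.begin(), f.end(), 0.0);
  energies[0] = energies[1] = energies[2] = 0.0;
  double epair = 0.0;
  bool thermo = (gamma != 0.0 || sigma != 0.0);
  for_each_pair(N, x, L, rc, [&](int i, int j, const double* d, double r) {
    double w = 1.0 - r / rc;
    double a = atab(sp[i], sp[j]);
    double coeff = a * w; // conservative
    if (thermo) {
      double rhat[3] = { d[0]/r, d[1]/r, d[2]/r };
      double vij[3] = { v[3*i]-v[3*j], v[3*i+1]-v[3*j+1], v[3*i+2]-v[3*j+2] };
      double rv = rhat[0]*vij[0] + rhat[1]*vij[1] + rhat[2]*vij[2];
      uint32_t lo = (uint32_t)std::min(i, j), hi = (uint32_t)std::max(i, j);
      double z = zeta_pair(seed, step, lo, hi, gaussian);
      coeff += -gamma * w * w * rv + sigma * w * z * inv_sqrt_dt;
    }
    double cr = coeff / r;
    for (int k2 = 0; k2 < 3; ++k2) {
      f[3*i+k2] += cr * d[k2];
      f[3*j+k2] -= cr * d[k2];
    }
    epair += 0.5 * a * rc * w * w;
  });
  energies[0] = epair;

  int nb = bonds.nrow();
  double ebond = 0.0;
  for (int b = 0; b < nb; ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    double d[3] = { x[3*i]-x[3*j], x[3*i+1]-x[3*j+1], x[3*i+2]-x[3*j+2] };
    min_image(d, L);
    double r = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
    double ks = bks[b], rs = brs[b];
    if (r < 1e-12) { // coincident bonded beads: deterministic epsilon shift
      d[0] = 1e-6; d[1] = 0.0; d[2] = 0.0; r = 1e-6;
    }
    double coeff = ks * (1.0 - r / rs) / r;
    for (int k2 = 0; k2 < 3; ++k2) {
      f[3*i+k2] += coeff * d[k2];
      f[3*j+k2] -= coeff * d[k2];
    }
    double dr = r - rs;
    ebond += 0.5 * (ks / rs) * dr * dr;
  }
  energies[1] = ebond;

  int na = angles.nrow();
  double eang = 0.0;
  for (int a2 = 0; a2 < na; ++a2) {
    int i = angles(a2, 0), j = angles(a2, 1), k = angles(a2, 2);
    double u[3] = { x[3*i]-x[3*j], x[3*i+1]-x[3*j+1], x[3*i+2]-x[3*j+2] };
    double w[3] = { x[3*k]-x[3*j], x[3*k+1]-x[3*j+1], x[3*k+2]-x[3*j+2] };
    min_image(u, L); min_image(w, L);
    double fi[3], fk[3];
    eang += angle_force(u, w, akt[a2], at0[a2], fi, fk);
    for (int d2 = 0; d2 < 3; ++d2) {
      f[3*i+d2] += fi[d2];
      f[3*k+d2] += fk[d2];
      f[3*j+d2] -= fi[d2] + fk[d2];
    }
  }
  energies[2] = eang;
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, NumericMatrix vel, IntegerVector species,
                NumericVector box, NumericMatrix atab, double rc,
                double gamma, double sigma, double dt,
                double seed, double step, bool gaussian,
                IntegerMatrix bonds, NumericVector bond_ks, NumericVector bond_rs,
                IntegerMatrix angles, NumericVector angle_kt, NumericVector angle_t0) {
  int N = pos.nrow();
  std::vector<double> x(3 * N), v(3 * N), f(3 * N);
  std::vector<int> sp(N);
  double L[3] = { box[0], box[1], box[2] };
  for (int i = 0; i < N; ++i) {
    for (int k = 0; k < 3; ++k) { x[3*i+k] = pos(i, k); v[3*i+k] = vel(i, k); }
    sp[i] = species[i] - 1;
  }
  double en[3];
  double isd = dt > 0 ? 1.0 / std::sqrt(dt) : 0.0;
  compute_forces(N, x, v, sp, L, atab, rc, gamma, sigma, isd,
                 (uint64_t)seed, (uint64_t)step, gaussian,
                 bonds, bond_ks, bond_rs, angles, angle_kt, angle_t0, f, en);
  NumericMatrix F(N, 3);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) F(i, k) = f[3*i+k];
  return List::create(_["forces"] = F,
                      _["e_pair"] = en[0], _["e_bond"] = en[1],
                      _["e_angle"] = en[2]);
}

// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, NumericMatrix vel, IntegerVector species,
             NumericVector box, NumericMatrix atab, double rc,
             double gamma, double sigma, double dt, double lambda,
             IntegerMatrix bonds, NumericVector bond_ks, NumericVector bond_rs,
             IntegerMatrix angles, NumericVector angle_kt, NumericVector angle_t0,
             int nsteps, double seed, int step_offset,
             int swap_every, int n_slabs,
             int traj_every, int energy_every,
             int profile_bins, int profile_every, bool gaussian) {
  int N = pos.nrow();
  std::vector<double> x(3 * N), v(3 * N), f(3 * N), fnew(3 * N), vt(3 * N);
  std::vector<int> sp(N);
  double L[3] = { box[0], box[1], box[2] };
  for (int i = 0; i < N; ++i) {
    for (int k = 0; k < 3; ++k) { x[3*i+k] = wrap0L(pos(i, k), L[k]); v[3*i+k] = vel(i, k); }
    sp[i] = species[i] - 1;
  }
  double isd = dt > 0 ? 1.0 / std::sqrt(dt) : 0.0;
  uint64_t useed = (uint64_t)seed;
  double en[3];

  std::vector<int> e_step;
  std::vector<double> e_pair, e_bond, e_angle, e_kin, e_px;
  List frames;
  std::vector<int> frame_steps;
  std::vector<NumericMatrix> frame_pos, frame_vel;
  std::vector<double> vx_sum(profile_bins > 0 ? profile_bins : 1, 0.0);
  std::vector<double> vx_cnt(profile_bins > 0 ? profile_bins : 1, 0.0);
  double acc_px = 0.0;
  int n_swaps = 0, n_skipped = 0;

  compute_forces(N, x, v, sp, L, atab, rc, gamma, sigma, isd, useed,
                 (uint64_t)step_offset, gaussian,
                 bonds, bond_ks, bond_rs, angles, angle_kt, angle_t0, f, en);

  auto record_energy = [&](int gs) {
    double kin = 0.0;
    for (int i = 0; i < 3 * N; ++i) kin += v[i] * v[i];
    kin *= 0.5;
    e_step.push_back(gs); e_pair.push_back(en[0]); e_bond.push_back(en[1]);
    e_angle.push_back(en[2]); e_kin.push_back(kin); e_px.push_back(acc_px);
  };
  auto record_frame = [&](int gs) {
    NumericMatrix P(N, 3), V(N, 3);
    for (int i = 0; i < N; ++i)
      for (int k = 0; k < 3; ++k) { P(i, k) = x[3*i+k]; V(i, k) = v[3*i+k]; }
    frame_steps.push_back(gs); frame_pos.push_back(P); frame_vel.push_back(V);
  };

  for (int s = 1; s <= nsteps; ++s) {
    int gs = step_offset + s;
    // position update + predicted velocity
    for (int i = 0; i < 3 * N; ++i) {
      x[i] += dt * v[i] + 0.5 * dt * dt * f[i];
      vt[i] = v[i] + lambda * dt * f[i];
    }
    for (int i = 0; i < N; ++i)
      for (int k = 0; k < 3; ++k) x[3*i+k] = wrap0L(x[3*i+k], L[k]);
    // force at new positions with predicted velocities
    compute_forces(N, x, vt, sp, L, atab, rc, gamma, sigma, isd, useed,
                   (uint64_t)gs, gaussian,
                   bonds, bond_ks, bond_rs, angles, angle_kt, angle_t0, fnew, en);
    for (int i = 0; i < 3 * N; ++i) {
      v[i] += 0.5 * dt * (f[i] + fnew[i]);
      f[i] = fnew[i];
    }
    for (int i = 0; i < 3 * N; ++i) {
      if (!std::isfinite(x[i]))
        stop("non-finite coordinate at step %d: integration blow-up", gs);
    }
    // Muller-Plathe momentum swap between slab 0 and slab n_slabs/2
    if (swap_every > 0 && n_slabs >= 2 && gs % swap_every == 0) {
      double h = L[2] / n_slabs;
      int upper = n_slabs / 2;
      int ilo = -1, ihi = -1;
      double vlo = R_PosInf, vhi = R_NegInf;
      for (int i = 0; i < N; ++i) {
        int slab = (int)(x[3*i+2] / h);
        if (slab >= n_slabs) slab = n_slabs - 1;
        if (slab == 0 && v[3*i] < vlo) { vlo = v[3*i]; ilo = i; }
        if (slab == upper && v[3*i] > vhi) { vhi = v[3*i]; ihi = i; }
      }
      if (ilo >= 0 && ihi >= 0) {
        double tmp = v[3*ilo]; v[3*ilo] = v[3*ihi]; v[3*ihi] = tmp;
        acc_px += (vhi - vlo); // equal masses: momentum transferred
        ++n_swaps;
      } else {
        ++n_skipped;
      }
    }
    if (profile_every > 0 && profile_bins > 1 && gs % profile_every == 0) {
      double hb = L[2] / profile_bins;
      for (int i = 0; i < N; ++i) {
        int b = (int)(x[3*i+2] / hb);
        if (b >= profile_bins) b = profile_bins - 1;
        vx_sum[b] += v[3*i]; vx_cnt[b] += 1.0;
      }
    }
    if (energy_every > 0 && gs % energy_every == 0) record_energy(gs);
    if (traj_every > 0 && gs % traj_every == 0) record_frame(gs);
  }

  NumericMatrix Pf(N, 3), Vf(N, 3);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) { Pf(i, k) = x[3*i+k]; Vf(i, k) = v[3*i+k]; }
  List fr(frame_steps.size());
  for (size_t i = 0; i < frame_steps.size(); ++i)
    fr[i] = List::create(_["step"] = frame_steps[i],
                         _["pos"] = frame_pos[i], _["vel"] = frame_vel[i]);
  return List::create(
    _["pos"] = Pf, _["vel"] = Vf, _["step"] = step_offset + nsteps,
    _["frames"] = fr,
    _["energy"] = List::create(_["step"] = e_step, _["pair"] = e_pair,
                               _["bond"] = e_bond, _["angle"] = e_angle,
                               _["kinetic"] = e_kin, _["acc_px"] = e_px),
    _["acc_px"] = acc_px, _["n_swaps"] = n_swaps, _["n_skipped"] = n_skipped,
    _["vx_sum"] = NumericVector(vx_sum.begin(), vx_sum.end()),
    _["vx_count"] = NumericVector(vx_cnt.begin(), vx_cnt.end()));
}

// [[Rcpp::export]]
List cpp_neighbor_pairs(NumericMatrix pos, NumericVector box, double cutoff) {
  int N = pos.nrow();
  std::vector<double> x(3 * N);
  double L[3] = { box[0], box[1], box[2] };
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) x[3*i+k] = wrap0L(pos(i, k), L[k]);
  std::vector<int> ii, jj;
  std::vector<double> rr, dx, dy, dz;
  for_each_pair(N, x, L, cutoff, [&](int i, int j, const double* d, double r) {
    ii.push_back(i + 1); jj.push_back(j + 1); rr.push_back(r);
    dx.push_back(d[0]); dy.push_back(d[1]); dz.push_back(d[2]);
  });
  return List::create(_["i"] = ii, _["j"] = jj, _["r"] = rr,
                      _["dx"] = dx, _["dy"] = dy, _["dz"] = dz);
}

// ---------------------------------------------------------------------------
// Irving-Kirkwood slab-resolved pressure tensor (diagonal components).
// Kinetic term goes to the bead's slab; each pairwise virial term is
// distributed over the slabs crossed by the minimum-image i-j segment,
// proportional to the segment length inside each slab. Angle terms are
// decomposed into the two vertex-to-end segments (force on i paired with
// r_i - r_j, force on k with r_k - r_j), which preserves the identity
// slab-sum == global virial exactly.
// ---------------------------------------------------------------------------
static void ik_distribute(double z0, double dz, double Lz, int n_slabs,
                          const double* w, std::vector<double>* acc) {
  double h = Lz / n_slabs;
  double adz = std::fabs(dz);
  if (adz < 1e-12) {
    int k = (int)(wrap0L(z0, Lz) / h);
    if (k >= n_slabs) k = n_slabs - 1;
    for (int c = 0; c < 3; ++c) acc[c][k] += w[c];
    return;
  }
  double z = wrap0L(z0, Lz);
  double sgn = dz > 0 ? 1.0 : -1.0;
  double remaining = adz;
  int k = (int)(z / h);
  if (k >= n_slabs) k = n_slabs - 1;
  int guard = 0;
  while (remaining > 1e-12 && guard++ < 4 * n_slabs + 8) {
    double to_edge = (sgn > 0) ? ((k + 1) * h - z) : (z - k * h);
    if (to_edge < 1e-12) to_edge = h; // sitting on an edge: take a full slab
    double step = std::min(remaining, to_edge);
    double frac = step / adz;
    for (int c = 0; c < 3; ++c) acc[c][k] += frac * w[c];
    remaining -= step;
    if (remaining <= 1e-12) break;
    if (sgn > 0) {
      k += 1; if (k >= n_slabs) k = 0;
      z = k * h;
    } else {
      k -= 1; if (k < 0) k = n_slabs - 1;
      z = (k + 1) * h;
    }
  }
}

// [[Rcpp::export]]
List cpp_pressure_profile(NumericMatrix pos, NumericMatrix vel,
                          IntegerVector species, NumericVector box,
                          NumericMatrix atab, double rc,
                          IntegerMatrix bonds, NumericVector bond_ks,
                          NumericVector bond_rs,
                          IntegerMatrix angles, NumericVector angle_kt,
                          NumericVector angle_t0, int n_slabs) {
  int N = pos.nrow();
  std::vector<double> x(3 * N);
  std::vector<int> sp(N);
  double L[3] = { box[0], box[1], box[2] };
  for (int i = 0; i < N; ++i) {
    for (int k = 0; k < 3; ++k) x[3*i+k] = wrap0L(pos(i, k), L[k]);
    sp[i] = species[i] - 1;
  }
  std::vector<double> kin[3], vir[3];
  for (int c = 0; c < 3; ++c) {
    kin[c].assign(n_slabs, 0.0);
    vir[c].assign(n_slabs, 0.0);
  }
  double h = L[2] / n_slabs;
  for (int i = 0; i < N; ++i) {
    int k = (int)(x[3*i+2] / h);
    if (k >= n_slabs) k = n_slabs - 1;
    for (int c = 0; c < 3; ++c) kin[c][k] += vel(i, c) * vel(i, c);
  }
  // conservative pair virial
  for_each_pair(N, x, L, rc, [&](int i, int j, const double* d, double r) {
    double a = atab(sp[i], sp[j]);
    double coeff = a * (1.0 - r / rc) / r; // F_i = coeff * d
    double w[3] = { coeff * d[0] * d[0], coeff * d[1] * d[1], coeff * d[2] * d[2] };
    // segment from bead i (z = x[3i+2]) towards j: displacement -d[2]
    ik_distribute(x[3*i+2], -d[2], L[2], n_slabs, w, vir);
  });
  // bond virial
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    double d[3] = { x[3*i]-x[3*j], x[3*i+1]-x[3*j+1], x[3*i+2]-x[3*j+2] };
    min_image(d, L);
    double r = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
    if (r < 1e-12) continue;
    double coeff = bond_ks[b] * (1.0 - r / bond_rs[b]) / r;
    double w[3] = { coeff * d[0] * d[0], coeff * d[1] * d[1], coeff * d[2] * d[2] };
    ik_distribute(x[3*i+2], -d[2], L[2], n_slabs, w, vir);
  }
  // angle virial: two segments anchored at the vertex j
  for (int a2 = 0; a2 < angles.nrow(); ++a2) {
    int i = angles(a2, 0), j = angles(a2, 1), k = angles(a2, 2);
    double u[3] = { x[3*i]-x[3*j], x[3*i+1]-x[3*j+1], x[3*i+2]-x[3*j+2] };
    double v2[3] = { x[3*k]-x[3*j], x[3*k+1]-x[3*j+1], x[3*k+2]-x[3*j+2] };
    min_image(u, L); min_image(v2, L);
    double fi[3], fk[3];
    angle_force(u, v2, angle_kt[a2], angle_t0[a2], fi, fk);
    double wi[3] = { fi[0]*u[0], fi[1]*u[1], fi[2]*u[2] };
    double wk[3] = { fk[0]*v2[0], fk[1]*v2[1], fk[2]*v2[2] };
    ik_distribute(x[3*i+2], -u[2], L[2], n_slabs, wi, vir);
    ik_distribute(x[3*k+2], -v2[2], L[2], n_slabs, wk, vir);
  }
  double slab_vol = L[0] * L[1] * h;
  NumericMatrix P(n_slabs, 3), K(n_slabs, 3), W(n_slabs, 3);
  for (int k = 0; k < n_slabs; ++k)
    for (int c = 0; c < 3; ++c) {
      K(k, c) = kin[c][k] / slab_vol;
      W(k, c) = vir[c][k] / slab_vol;
      P(k, c) = K(k, c) + W(k, c);
    }
  return List::create(_["pressure"] = P, _["kinetic"] = K, _["virial"] = W,
                      _["slab_volume"] = slab_vol);
}
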