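#include "model.h"
#include "rng.h"
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// SRD/MPCD solvent: ballistic streaming + cell-wise stochastic rotation of
// velocities relative to the cell centre-of-mass, with polymer beads taking
// part in the collision as cell members (Malevanets-Kapral coupling). The
// rotation conserves per-cell momentum and kinetic energy exactly; an
// optional cell-level Maxwell-Boltzmann rescaling (MBS) thermostat keeps the
// bath canonical when the motor pumps work into a finite box.
// ---------------------------------------------------------------------------

struct SRDPar {
  double a;        // collision cell size
  double alpha;    // rotation angle (radians)
  int interval;    // MD steps between collisions
  double L;        // periodic box edge (box centred on the origin)
  double m_s;      // solvent particle mass
  bool grid_shift;
  bool thermostat;
  double Tstar;
};

static inline double wrap(double x, double L) {
  // periodic wrap into [-L/2, L/2)
  return x - L * std::floor(x / L + 0.5);
}

static inline int cell_coord(double x, double shift, double a, double L, int nc) {
  // map coordinate (box centred at origin) to a shifted cell index
  double w = x + 0.5 * L - shift;
  w -= L * std::floor(w / L);
  int c = (int)(w / a);
  if (c >= nc) c = nc - 1;
  if (c < 0) c = 0;
  return c;
}

// One collision step over solvent particles and beads. sx/sv are 3*Ns,
// bx/bv are 3*Nb (bead mass 1). If fixed_axis is non-null every occupied
// cell uses that rotation axis (unit length) - used by the unit tests.
// Buffers persist across calls via the Collider to keep the hot loop
// allocation-free. The MBS thermostat rescaling is applied on a subset of
// collision steps (thermostat_now); the rotation itself conserves per-cell
// momentum and energy on every step.
struct Collider {
  std::vector<int> cell, ccount;
  std::vector<double> cmass, cmom, ckin, axis, scale;

  void collide(std::vector<double> &sv, const std::vector<double> &sx,
               std::vector<double> &bv, const std::vector<double> &bx,
               int Ns, int Nb, const SRDPar &S, pp::RNG &rng,
               bool thermostat_now, const double *fixed_shift,
               const double *fixed_axis) {
    const int nc = (int)std::lround(S.L / S.a);
    const int ncells = nc * nc * nc;
    double shift[3] = {0.0, 0.0, 0.0};
    if (fixed_shift) {
      shift[0] = fixed_shift[0]; shift[1] = fixed_shift[1]; shift[2] = fixed_shift[2];
    } else if (S.grid_shift) {
      for (int k = 0; k < 3; ++k) shift[k] = rng.unif(-0.5 * S.a, 0.5 * S.a);
    }

    const int Ntot = Ns + Nb;
    cell.resize(Ntot);
    cmass.assign(ncells, 0.0);
    cmom.assign(3 * ncells, 0.0);
    ckin.assign(ncells, 0.0);
    ccount.assign(ncells, 0);

    for (int i = 0; i < Ntot; ++i) {
      const bool bead = i >= Ns;
      const double *px = bead ? &bx[3 * (i - Ns)] : &sx[3 * i];
      const double *pv = bead ? &bv[3 * (i - Ns)] : &sv[3 * i];
      const double m = bead ? 1.0 : S.m_s;
      const int cx = cell_coord(px[0], shift[0], S.a, S.L, nc);
      const int cy = cell_coord(px[1], shift[1], S.a, S.L, nc);
      const int cz = cell_coord(px[2], shift[2], S.a, S.L, nc);
      const int c = (cz * nc + cy) * nc + cx;
      cell[i] = c;
      cmass[c] += m;
      cmom[3 * c] += m * pv[0]; cmom[3 * c + 1] += m * pv[1]; cmom[3 * c + 2] += m * pv[2];
      if (thermostat_now)
        ckin[c] += 0.5 * m * (pv[0] * pv[0] + pv[1] * pv[1] + pv[2] * pv[2]);
      ccount[c] += 1;
    }

    // per occupied cell: rotation axis and (optional) thermostat scale
    axis.resize(3 * ncells);
    scale.assign(ncells, 1.0);
    const double ca = std::cos(S.alpha), sa = std::sin(S.alpha);
    for (int c = 0; c < ncells; ++c) {
      if (ccount[c] == 0) continue;
      double ax[3];
      if (fixed_axis) { ax[0] = fixed_axis[0]; ax[1] = fixed_axis[1]; ax[2] = fixed_axis[2]; }
      else rng.unit_vector(ax);
      axis[3 * c] = ax[0]; axis[3 * c + 1] = ax[1]; axis[3 * c + 2] = ax[2];
      if (thermostat_now && ccount[c] >= 2) {
        const double ekrel = ckin[c] -
            0.5 * (cmom[3 * c] * cmom[3 * c] + cmom[3 * c + 1] * cmom[3 * c + 1] +
                   cmom[3 * c + 2] * cmom[3 * c + 2]) / cmass[c];
        if (ekrel > 1e-12) {
          const double target = rng.gamma(1.5 * (ccount[c] - 1)) * S.Tstar;
          scale[c] = std::sqrt(target / ekrel);
        }
      }
    }

    for (int i = 0; i < Ntot; ++i) {
      const int c = cell[i];
      double *pv = (i >= Ns) ? &bv[3 * (i - Ns)] : &sv[3 * i];
      const double vcx = cmom[3 * c] / cmass[c];
      const double vcy = cmom[3 * c + 1] / cmass[c];
      const double vcz = cmom[3 * c + 2] / cmass[c];
      const double ux = pv[0] - vcx, uy = pv[1] - vcy, uz = pv[2] - vcz;
      const double kx = axis[3 * c], ky = axis[3 * c + 1], kz = axis[3 * c + 2];
      const double kd = kx * ux + ky * uy + kz * uz;
      // Rodrigues rotation of the relative velocity about the cell axis
      double rx = ux * ca + (ky * uz - kz * uy) * sa + kx * kd * (1.0 - ca);
      double ry = uy * ca + (kz * ux - kx * uz) * sa + ky * kd * (1.0 - ca);
      double rz = uz * ca + (kx * uy - ky * ux) * sa + kz * kd * (1.0 - ca);
      const double lam = scale[c];
      pv[0] = vcx + lam * rx; pv[1] = vcy + lam * ry; pv[2] = vcz + lam * rz;
    }
  }
};

static void srd_collide(std::vector<double> &sv, const std::vector<double> &sx,
                        std::vector<double> &bv, const std::vector<double> &bx,
                        int Ns, int Nb, const SRDPar &S, pp::RNG &rng,
                        const double *fixed_shift, const double *fixed_axis) {
  Collider col;
  col.collide(sv, sx, bv, bx, Ns, Nb, S, rng, S.thermostat, fixed_shift,
              fixed_axis);
}

static void stream_solvent(std::vector<double> &sx, const std::vector<double> &sv,
                           int Ns, double dt, double L) {
  for (int i = 0; i < 3 * Ns; ++i) sx[i] = wrap(sx[i] + sv[i] * dt, L);
}

static void resample_solvent(std::vector<double> &sv, int Ns, double Tstar,
                             double m_s, pp::RNG &rng) {
  const double sd = std::sqrt(Tstar / m_s);
  for (int i = 0; i < 3 * Ns; ++i) sv[i] = sd * rng.norm();
}

// Motor drive with force-velocity saturation: the full feeding force acts
// on a captured bead only while its inward radial speed is below v_cap
// (motors stall above a maximum translocation speed). This bounds the work
// rate so the drive cannot outrun the solvent friction and launch the
// chain ballistically. The exposed total_forces()/motor_force() contracts
// keep the plain position-only constant force; this gate lives in the
// integrator alone.
static const double MOTOR_VCAP = 1.0;   // stall speed, ~ thermal
static const double MOTOR_RSTALL = 1.16; // bond length at which the FENE
                                         // tension equals the motor force

static void motor_kick(const std::vector<double> &x,
                       const std::vector<double> &v, std::vector<double> &fm,
                       int N, const Geom &G) {
  std::fill(fm.begin(), fm.end(), 0.0);
  if (!G.enabled || G.motor_F <= 0.0) return;
  for (int i = 0; i < N; ++i) {
    const double px = x[3 * i], py = x[3 * i + 1], pz = x[3 * i + 2];
    const double rho2 = px * px + py * py;
    if (G.tail && rho2 >= G.pore_radius * G.pore_radius) continue;
    const double dx = px, dy = py, dz = pz - G.R;
    if (dx * dx + dy * dy + dz * dz >= G.motor_capture * G.motor_capture)
      continue;
    const double r = std::sqrt(rho2 + pz * pz);
    if (r <= 1e-12) continue;
    // stall on speed: no work above the maximum translocation speed
    const double vin = -(v[3 * i] * px + v[3 * i + 1] * py +
                         v[3 * i + 2] * pz) / r;
    if (vin >= MOTOR_VCAP) continue;
    // stall on load: the motor cannot stretch the backbone ahead beyond
    // its own stall tension (bond at MOTOR_RSTALL carries ~ motor_F)
    if (i + 1 < N) {
      const double bx = x[3 * i + 3] - px, by = x[3 * i + 4] - py,
                   bz = x[3 * i + 5] - pz;
      if (bx * bx + by * by + bz * bz > MOTOR_RSTALL * MOTOR_RSTALL) continue;
    }
    fm[3 * i]     = -G.motor_F * px / r;
    fm[3 * i + 1] = -G.motor_F * py / r;
    fm[3 * i + 2] = -G.motor_F * pz / r;
  }
}

// ---------------------------------------------------------------------------
// Hybrid MD <-> SRD driver
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run(NumericMatrix pos0, NumericMatrix vel0, NumericMatrix spos0,
             NumericMatrix svel0, List pot, List geom, List srd, double Tstar,
             double dt, double n_steps_d, bool motor_on, bool hydro,
             double sample_stride_d, int stop_mode, int anchor,
             double seed_master, double seed_stream) {
  const int N = pos0.nrow();
  const int Ns = spos0.nrow();
  const long n_steps = (long)n_steps_d;
  const long sample_stride = (long)(sample_stride_d > 0 ? sample_stride_d : n_steps_d);
  PotParams P = pot_from_list(pot, Tstar);
  Geom G = geom_from_list(geom);

  SRDPar S;
  S.a = as<double>(srd["cell_size"]);
  S.alpha = as<double>(srd["rotation_angle_deg"]) * M_PI / 180.0;
  S.interval = as<int>(srd["srd_interval"]);
  S.L = as<double>(srd["box_edge"]);
  S.m_s = as<double>(srd["solvent_mass"]);
  S.grid_shift = as<bool>(srd["grid_shift"]);
  S.thermostat = as<bool>(srd["thermostat"]);
  S.Tstar = Tstar;

  pp::RNG rng((std::uint64_t)seed_master, (std::uint64_t)seed_stream);
  Collider col;

  std::vector<double> x(3 * N), v(3 * N), f(3 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) { x[3 * i + k] = pos0(i, k); v[3 * i + k] = vel0(i, k); }
  std::vector<double> sx(3 * Ns), sv(3 * Ns), bwrap(3 * N);
  for (int i = 0; i < Ns; ++i)
    for (int k = 0; k < 3; ++k) { sx[3 * i + k] = spos0(i, k); sv[3 * i + k] = svel0(i, k); }

  int err;
  double U = bead_forces(x, f, N, P, G, false, &err);
  if (err >= 0) stop("initial state invalid: bead %d overstretched/degenerate", err + 1);
  std::vector<double> fm(3 * N, 0.0);

  std::vector<double> ts_step, ts_in, ts_tail;
  long event_step = -1;
  bool done = false;
  double acc_Tb = 0.0, acc_Ts = 0.0;
  long n_T = 0;

  auto occupancy = [&](int *n_in, int *n_tl, bool *packed, bool *ejected) {
    int ni = 0, nt = 0, nin_sphere = 0, nfree = 0;
    for (int i = 0; i < N; ++i) {
      const int reg = classify_point(x[3 * i], x[3 * i + 1], x[3 * i + 2], G);
      if (reg == REG_INSIDE) ++ni;
      else if (reg == REG_TAIL) ++nt;
      const double r2 = x[3 * i] * x[3 * i] + x[3 * i + 1] * x[3 * i + 1] +
                        x[3 * i + 2] * x[3 * i + 2];
      if (r2 < G.R * G.R) ++nin_sphere;
      if (reg == REG_OUTSIDE) ++nfree;
    }
    *n_in = ni; *n_tl = nt;
    *packed = (nin_sphere == N);
    *ejected = (nfree == N);
  };

  auto record = [&](long step) {
    int ni, nt; bool pk, ej;
    occupancy(&ni, &nt, &pk, &ej);
    ts_step.push_back((double)step);
    ts_in.push_back((double)ni);
    ts_tail.push_back((double)nt);
  };
  record(0);

  const double half = 0.5 * dt;
  for (long step = 1; step <= n_steps && !done; ++step) {
    if (motor_on) motor_kick(x, v, fm, N, G);
    if (anchor >= 0) {
      f[3 * anchor] = f[3 * anchor + 1] = f[3 * anchor + 2] = 0.0;
      fm[3 * anchor] = fm[3 * anchor + 1] = fm[3 * anchor + 2] = 0.0;
      v[3 * anchor] = v[3 * anchor + 1] = v[3 * anchor + 2] = 0.0;
    }
    for (int i = 0; i < 3 * N; ++i) v[i] += half * (f[i] + fm[i]);
    for (int i = 0; i < 3 * N; ++i) x[i] += dt * v[i];
    U = bead_forces(x, f, N, P, G, false, &err);
    if (err >= 0)
      stop("integrator instability at step %ld, bead %d (overstretched bond)",
           step, err + 1);
    if (anchor >= 0) f[3 * anchor] = f[3 * anchor + 1] = f[3 * anchor + 2] = 0.0;
    for (int i = 0; i < 3 * N; ++i) v[i] += half * (f[i] + fm[i]);
    if (anchor >= 0) v[3 * anchor] = v[3 * anchor + 1] = v[3 * anchor + 2] = 0.0;

    if (Ns > 0 && step % S.interval == 0) {
      stream_solvent(sx, sv, Ns, S.interval * dt, S.L);
      for (int i = 0; i < 3 * N; ++i) bwrap[i] = wrap(x[i], S.L);
      const bool tstat_now = S.thermostat;
      col.collide(sv, sx, v, bwrap, Ns, N, S, rng, tstat_now, nullptr,
                  nullptr);
      if (!hydro) resample_solvent(sv, Ns, Tstar, S.m_s, rng);
      if (anchor >= 0) v[3 * anchor] = v[3 * anchor + 1] = v[3 * anchor + 2] = 0.0;

      // running kinetic temperatures + termination test (cheap, every collision)
      double kb = 0.0, ks = 0.0;
      for (int i = 0; i < 3 * N; ++i) kb += v[i] * v[i];
      for (int i = 0; i < 3 * Ns; ++i) ks += sv[i] * sv[i];
      acc_Tb += kb / (3.0 * N);
      acc_Ts += S.m_s * ks / (3.0 * Ns);
      ++n_T;

      if (stop_mode != 0) {
        int ni, nt; bool pk, ej;
        occupancy(&ni, &nt, &pk, &ej);
        if ((stop_mode == 1 && pk) || (stop_mode == 2 && ej)) {
          event_step = step;
          done = true;
        }
      }
    }
    if (step % sample_stride == 0 || done || step == n_steps) record(step);
  }

  NumericMatrix pos(N, 3), vel(N, 3), spos(Ns, 3), svel(Ns, 3);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) { pos(i, k) = x[3 * i + k]; vel(i, k) = v[3 * i + k]; }
  for (int i = 0; i < Ns; ++i)
    for (int k = 0; k < 3; ++k) { spos(i, k) = sx[3 * i + k]; svel(i, k) = sv[3 * i + k]; }

  const long steps_done = done ? event_step : n_steps;
  return List::create(
      _["pos"] = pos, _["vel"] = vel, _["spos"] = spos, _["svel"] = svel,
      _["steps_done"] = (double)steps_done,
      _["ts_step"] = NumericVector(ts_step.begin(), ts_step.end()),
      _["ts_inside"] = NumericVector(ts_in.begin(), ts_in.end()),
      _["ts_tail"] = NumericVector(ts_tail.begin(), ts_tail.end()),
      _["event_step"] = (double)event_step,
      _["mean_T_beads"] = n_T ? acc_Tb / n_T : NA_REAL,
      _["mean_T_solvent"] = n_T ? acc_Ts / n_T : NA_REAL);
}

// ---------------------------------------------------------------------------
// Plain velocity-Verlet for beads only (NVE checks, wall-bounce audits)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_velocity_verlet(NumericMatrix pos0, NumericMatrix vel0, List pot,
                         List geom, double Tstar, bool motor_on, double dt,
                         double n_steps_d, double energy_stride_d) {
  const int N = pos0.nrow();
  const long n_steps = (long)n_steps_d;
  const long estride = (long)(energy_stride_d > 0 ? energy_stride_d : n_steps_d);
  PotParams P = pot_from_list(pot, Tstar);
  Geom G = geom_from_list(geom);
  std::vector<double> x(3 * N), v(3 * N), f(3 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) { x[3 * i + k] = pos0(i, k); v[3 * i + k] = vel0(i, k); }
  int err;
  double U = bead_forces(x, f, N, P, G, motor_on, &err);
  if (err >= 0) stop("initial state invalid near bead %d", err + 1);

  std::vector<double> energies;
  auto total_E = [&](double Upot) {
    double K = 0.0;
    for (int i = 0; i < 3 * N; ++i) K += 0.5 * v[i] * v[i];
    return K + Upot;
  };
  energies.push_back(total_E(U));

  const double half = 0.5 * dt;
  for (long step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < 3 * N; ++i) v[i] += half * f[i];
    for (int i = 0; i < 3 * N; ++i) x[i] += dt * v[i];
    U = bead_forces(x, f, N, P, G, motor_on, &err);
    if (err >= 0)
      stop("integrator instability at step %ld, bead %d (overstretched bond)",
           step, err + 1);
    for (int i = 0; i < 3 * N; ++i) v[i] += half * f[i];
    if (step % estride == 0) energies.push_back(total_E(U));
  }

  NumericMatrix pos(N, 3), vel(N, 3);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) { pos(i, k) = x[3 * i + k]; vel(i, k) = v[3 * i + k]; }
  return List::create(_["pos"] = pos, _["vel"] = vel,
                      _["energies"] = NumericVector(energies.begin(), energies.end()));
}

// ---------------------------------------------------------------------------
// Solvent helpers exposed to R
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_init_solvent(int n, double L, double Tstar, double m_s,
                      double seed_master, double seed_stream) {
  pp::RNG rng((std::uint64_t)seed_master, (std::uint64_t)seed_stream);
  NumericMatrix pos(n, 3), vel(n, 3);
  const double sd = std::sqrt(Tstar / m_s);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      pos(i, k) = rng.unif(-0.5 * L, 0.5 * L);
      vel(i, k) = sd * rng.norm();
    }
  // remove net drift, then rescale to the exact target temperature
  for (int k = 0; k < 3; ++k) {
    double mu = 0.0;
    for (int i = 0; i < n; ++i) mu += vel(i, k);
    mu /= n;
    for (int i = 0; i < n; ++i) vel(i, k) -= mu;
  }
  double k2 = 0.0;
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) k2 += vel(i, k) * vel(i, k);
  const double Tnow = m_s * k2 / (3.0 * n);
  const double lam = std::sqrt(Tstar / Tnow);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) vel(i, k) *= lam;
  return List::create(_["pos"] = pos, _["vel"] = vel);
}

// [[Rcpp::export]]
List cpp_srd_collide(NumericMatrix spos, NumericMatrix svel, NumericMatrix bpos,
                     NumericMatrix bvel, double cell_size, double box_edge,
                     double alpha_deg, double m_s, double Tstar, bool thermostat,
                     bool grid_shift, Nullable<NumericVector> shift,
                     Nullable<NumericVector> axis, double seed_master,
                     double seed_stream) {
  const int Ns = spos.nrow(), Nb = bpos.nrow();
  SRDPar S;
  S.a = cell_size; S.L = box_edge; S.alpha = alpha_deg * M_PI / 180.0;
  S.m_s = m_s; S.grid_shift = grid_shift; S.thermostat = thermostat;
  S.Tstar = Tstar; S.interval = 1;
  pp::RNG rng((std::uint64_t)seed_master, (std::uint64_t)seed_stream);
  std::vector<double> sx(3 * Ns), sv(3 * Ns), bx(3 * Nb), bv(3 * Nb);
  for (int i = 0; i < Ns; ++i)
    for (int k = 0; k < 3; ++k) { sx[3 * i + k] = spos(i, k); sv[3 * i + k] = svel(i, k); }
  for (int i = 0; i < Nb; ++i)
    for (int k = 0; k < 3; ++k) { bx[3 * i + k] = wrap(bpos(i, k), S.L); bv[3 * i + k] = bvel(i, k); }
  double shv[3], axv[3];
  const double *psh = nullptr, *pax = nullptr;
  if (shift.isNotNull()) {
    NumericVector s(shift); shv[0] = s[0]; shv[1] = s[1]; shv[2] = s[2]; psh = shv;
  }
  if (axis.isNotNull()) {
    NumericVector a(axis);
    const double n = std::sqrt(a[0] * a[0] + a[1] * a[1] + a[2] * a[2]);
    axv[0] = a[0] / n; axv[1] = a[1] / n; axv[2] = a[2] / n; pax = axv;
  }
  srd_collide(sv, sx, bv, bx, Ns, Nb, S, rng, psh, pax);
  NumericMatrix osv(Ns, 3), obv(Nb, 3);
  for (int i = 0; i < Ns; ++i)
    for (int k = 0; k < 3; ++k) osv(i, k) = sv[3 * i + k];
  for (int i = 0; i < Nb; ++i)
    for (int k = 0; k < 3; ++k) obv(i, k) = bv[3 * i + k];
  return List::create(_["svel"] = osv, _["bvel"] = obv);
}

// [[Rcpp::export]]
NumericMatrix cpp_resample_velocities(int n, double Tstar, double m_s,
                                      double seed_master, double seed_stream) {
  pp::RNG rng((std::uint64_t)seed_master, (std::uint64_t)seed_stream);
  NumericMatrix vel(n, 3);
  const double sd = std::sqrt(Tstar / m_s);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) vel(i, k) = sd * rng.norm();
  return vel;
}

// [[Rcpp::export]]
NumericVector cpp_grid_shift_draws(int n, double cell_size, double seed_master,
                                   double seed_stream) {
  pp::RNG rng((std::uint64_t)seed_master, (std::uint64_t)seed_stream);
  NumericVector out(3 * n);
  for (int i = 0; i < 3 * n; ++i) out[i] = rng.unif(-0.5 * cell_size, 0.5 * cell_size);
  out.attr("dim") = IntegerVector::create(3, n);
  return out;
}
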