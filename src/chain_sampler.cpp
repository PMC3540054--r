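#include "model.h"
#include "rng.h"
#include <cmath>
#include <vector>

using namespace Rcpp;

// Free-chain conformational sampler: BAOAB Langevin integration of the
// bead-spring chain with no capsid and no solvent. Equilibrium conformational
// statistics (bond lengths, bond-angle distribution, persistence length) are
// ensemble properties independent of the dynamics, so this cheap thermostat
// is used for calibration instead of the full SRD machinery.

// [[Rcpp::export]]
NumericVector cpp_langevin_chain(int n_beads, List pot, double Tstar,
                                 double friction, double dt, double n_equil_d,
                                 int n_conf, double stride_d,
                                 double seed_master, double seed_stream) {
  const int N = n_beads;
  const long n_equil = (long)n_equil_d;
  const long stride = (long)stride_d;
  PotParams P = pot_from_list(pot, Tstar);
  Geom G; G.enabled = false; G.tail = false;
  G.R = G.pore_radius = G.wall_k = G.wall_range = 0.0;
  G.tail_len = G.tail_rad = G.tail_k = G.motor_F = G.motor_capture = 0.0;

  pp::RNG rng((std::uint64_t)seed_master, (std::uint64_t)seed_stream);

  // initial state drawn from the ideal worm-like-chain Boltzmann weight:
  // per joint, cos(theta) from the exact inverse CDF of exp(kappa~ cos),
  // uniform azimuth, with a self-avoidance guard so excluded volume only
  // needs a short MD fix-up. This removes the slow global-mode relaxation
  // a straight-rod start would require.
  std::vector<double> x(3 * N), v(3 * N), f(3 * N);
  const double b0 = 0.97 * P.lj_sigma;
  const double ktil = (P.kappa > 1e-8 ? P.kappa : 1e-8) / Tstar;
  {
    double dir[3] = {0.0, 0.0, 1.0};
    x[0] = x[1] = x[2] = 0.0;
    int backtracks = 0;
    for (int i = 1; i < N; ++i) {
      double nd[3];
      bool ok = false;
      for (int attempt = 0; attempt < 200 && !ok; ++attempt) {
        const double u = rng.unif();
        double c = 1.0 + std::log(u + (1.0 - u) * std::exp(-2.0 * ktil)) / ktil;
        if (c > 1.0) c = 1.0;
        if (c < -1.0) c = -1.0;
        const double st = std::sqrt(1.0 - c * c);
        const double phi = 6.283185307179586 * rng.unif();
        // orthonormal frame around dir
        double e1[3], e2[3];
        if (std::fabs(dir[2]) < 0.9) { e1[0] = -dir[1]; e1[1] = dir[0]; e1[2] = 0.0; }
        else { e1[0] = 0.0; e1[1] = -dir[2]; e1[2] = dir[1]; }
        double n1 = std::sqrt(e1[0]*e1[0] + e1[1]*e1[1] + e1[2]*e1[2]);
        for (int k = 0; k < 3; ++k) e1[k] /= n1;
        e2[0] = dir[1]*e1[2] - dir[2]*e1[1];
        e2[1] = dir[2]*e1[0] - dir[0]*e1[2];
        e2[2] = dir[0]*e1[1] - dir[1]*e1[0];
        for (int k = 0; k < 3; ++k)
          nd[k] = c * dir[k] + st * (std::cos(phi) * e1[k] + std::sin(phi) * e2[k]);
        double cand[3] = {x[3*(i-1)] + b0*nd[0], x[3*(i-1)+1] + b0*nd[1],
                          x[3*(i-1)+2] + b0*nd[2]};
        ok = true;
        for (int j = 0; j < i - 1 && ok; ++j) {
          const double ddx = cand[0] - x[3*j], ddy = cand[1] - x[3*j+1],
                       ddz = cand[2] - x[3*j+2];
          if (ddx*ddx + ddy*ddy + ddz*ddz < 0.81) ok = false;
        }
        if (ok) {
          x[3*i] = cand[0]; x[3*i+1] = cand[1]; x[3*i+2] = cand[2];
          dir[0] = nd[0]; dir[1] = nd[1]; dir[2] = nd[2];
        }
      }
      if (!ok) {
        // flexible chains can wall themselves in; back up and regrow
        if (++backtracks > 200)
          stop("could not draw a self-avoiding initial conformation");
        i = (i > 8) ? i - 6 : 1;
        if (i > 1) {
          double d0[3] = {x[3*i + 0] - x[3*(i-1) + 0],
                          x[3*i + 1] - x[3*(i-1) + 1],
                          x[3*i + 2] - x[3*(i-1) + 2]};
          const double n0 = std::sqrt(d0[0]*d0[0] + d0[1]*d0[1] + d0[2]*d0[2]);
          dir[0] = d0[0] / n0; dir[1] = d0[1] / n0; dir[2] = d0[2] / n0;
        } else {
          dir[0] = 0.0; dir[1] = 0.0; dir[2] = 1.0;
        }
        continue;
      }
    }
  }
  const double sdv = std::sqrt(Tstar);
  for (int i = 0; i < 3 * N; ++i) v[i] = sdv * rng.norm();

  int err;
  double U = bead_forces(x, f, N, P, G, false, &err);
  if (err >= 0) stop("sampler initial state invalid near bead %d", err + 1);

  const double c1 = std::exp(-friction * dt);
  const double c2 = std::sqrt((1.0 - c1 * c1) * Tstar);
  const double half = 0.5 * dt;

  NumericVector out((R_xlen_t)N * 3 * n_conf);
  long total = n_equil + (long)n_conf * stride;
  int stored = 0;
  for (long step = 1; step <= total; ++step) {
    for (int i = 0; i < 3 * N; ++i) v[i] += half * f[i];
    for (int i = 0; i < 3 * N; ++i) x[i] += half * v[i];
    for (int i = 0; i < 3 * N; ++i) v[i] = c1 * v[i] + c2 * rng.norm();
    for (int i = 0; i < 3 * N; ++i) x[i] += half * v[i];
    U = bead_forces(x, f, N, P, G, false, &err);
    if (err >= 0)
      stop("sampler instability at step %ld, bead %d", step, err + 1);
    for (int i = 0; i < 3 * N; ++i) v[i] += half * f[i];

    if (step > n_equil && (step - n_equil) % stride == 0 && stored < n_conf) {
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < 3; ++k)
          out[(R_xlen_t)stored * 3 * N + (R_xlen_t)k * N + i] = x[3 * i + k];
      ++stored;
    }
  }
  (void)U;
  out.attr("dim") = IntegerVector::create(N, 3, n_conf);
  return out;
}

// Deterministic 31-bit seed derivation for R-level RNG use.
// [[Rcpp::export]]
double cpp_derive_seed(double master, double stream) {
  std::uint64_t s = (std::uint64_t)master * 0x9E3779B97F4A7C15ULL +
                    (std::uint64_t)stream * 0xD1B54A32D192ED03ULL + 1ULL;
  std::uint64_t z = pp::splitmix64(s);
  return (double)(z % 2147483629ULL) + 1.0;
}
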