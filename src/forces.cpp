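#include "model.h"
#include <cmath>

using namespace Rcpp;

PotParams pot_from_list(const List &L, double Tstar) {
  PotParams P;
  P.fene_k   = as<double>(L["fene_k"]);
  P.fene_r0  = as<double>(L["fene_r0"]);
  P.lj_eps   = as<double>(L["lj_epsilon"]);
  P.lj_sigma = as<double>(L["lj_sigma"]);
  P.lj_cut   = as<double>(L["lj_cutoff"]);
  P.kappa    = as<double>(L["bend_kappa"]);
  P.charged  = as<bool>(L["charged"]);
  P.A        = as<double>(L["charge_prefactor"]);
  P.lambda_d = as<double>(L["debye_length"]);
  P.elec_cut = as<double>(L["elec_cutoff"]);
  P.Tstar    = Tstar;
  const double sr2 = (P.lj_sigma * P.lj_sigma) / (P.lj_cut * P.lj_cut);
  const double sr6 = sr2 * sr2 * sr2;
  P.lj_shift = -4.0 * P.lj_eps * (sr6 * sr6 - sr6);
  return P;
}

Geom geom_from_list(const List &L) {
  Geom G;
  G.enabled = as<bool>(L["enabled"]);
  if (!G.enabled) {
    G.R = G.pore_radius = G.wall_k = G.wall_range = 0.0;
    G.tail = false; G.tail_len = G.tail_rad = G.tail_k = 0.0;
    G.motor_F = G.motor_capture = 0.0;
    return G;
  }
  G.R             = as<double>(L["capsid_radius"]);
  G.pore_radius   = as<double>(L["pore_radius"]);
  G.wall_k        = as<double>(L["wall_stiffness"]);
  G.wall_range    = as<double>(L["wall_range"]);
  G.tail          = as<bool>(L["tail"]);
  G.tail_len      = as<double>(L["tail_length"]);
  G.tail_rad      = as<double>(L["tail_radius"]);
  G.tail_k        = as<double>(L["tail_stiffness"]);
  G.motor_F       = as<double>(L["motor_force"]);
  G.motor_capture = as<double>(L["motor_capture_radius"]);
  return G;
}

int classify_point(double px, double py, double pz, const Geom &G) {
  const double rho2 = px * px + py * py;
  const double r = std::sqrt(rho2 + pz * pz);
  // pore channel: cylinder of radius pore_radius spanning the wall shell
  if (rho2 < G.pore_radius * G.pore_radius && pz > G.R - G.wall_range &&
      pz < G.R + G.wall_range)
    return REG_PORE;
  if (G.tail && pz >= G.R + G.wall_range && pz <= G.R + G.tail_len &&
      rho2 < (G.tail_rad + 0.5) * (G.tail_rad + 0.5))
    return REG_TAIL;
  if (r < G.R) return REG_INSIDE;
  return REG_OUTSIDE;
}

// Wall repulsion at a point. The free space is (a) anywhere beyond the
// repulsive shell |r - R| >= wall_range, and (b) the pore: a cylindrical
// channel of the given radius through the upper hemisphere, opening into a
// cone of unit slope above the surface (the funnel-shaped portal mouth).
// The force is stiffness x (distance to the nearest free region), directed
// toward it, so a bead pressed onto the mouth slides into the waist instead
// of rattling on a hard rim. Piecewise smooth; the seams between branches
// are the documented pore-edge discontinuities.
static double wall_force_point(const double p[3], double f[3], const Geom &G,
                               double channel_radius) {
  f[0] = f[1] = f[2] = 0.0;
  if (!G.enabled || G.wall_k <= 0.0) return 0.0;
  const double rho2 = p[0] * p[0] + p[1] * p[1];
  const double rho = std::sqrt(rho2);
  const double r = std::sqrt(rho2 + p[2] * p[2]);
  const double s = r - G.R;  // signed distance to the sphere surface
  if (std::fabs(s) >= G.wall_range || r <= 1e-12) return 0.0;

  // with a tail attached the tube replaces the funnel: entry is through the
  // tail tip only, so the mouth above the surface stays cylindrical
  const double slope = G.tail ? 0.0 : 1.0;
  const double d_rad = G.wall_range - std::fabs(s);  // exit through a shell face

  double d_ch = -1.0;  // exit through the pore channel (upper half only)
  double nx = 0.0, ny = 0.0, nz = 0.0;
  if (p[2] > 0.0) {
    if (p[2] > G.R) {  // conical mouth above the surface
      const double chan = channel_radius + slope * (p[2] - G.R);
      if (rho < chan) return 0.0;  // inside the funnel: free
      const double inv = 1.0 / std::sqrt(1.0 + slope * slope);
      d_ch = (rho - chan) * inv;
      if (rho > 1e-12) {
        nx = -(p[0] / rho) * inv; ny = -(p[1] / rho) * inv;
        nz = slope * inv;
      }
    } else {  // cylindrical channel through the shell
      if (rho < channel_radius) return 0.0;  // inside the channel: free
      d_ch = rho - channel_radius;
      if (rho > 1e-12) { nx = -p[0] / rho; ny = -p[1] / rho; nz = 0.0; }
    }
  }

  if (d_ch >= 0.0 && d_ch < d_rad) {
    const double mag = G.wall_k * d_ch;
    f[0] = mag * nx; f[1] = mag * ny; f[2] = mag * nz;
    return 0.5 * G.wall_k * d_ch * d_ch;
  }
  const double mag = G.wall_k * d_rad;
  const double sgn = (s >= 0.0) ? 1.0 : -1.0;
  f[0] = sgn * mag * p[0] / r;
  f[1] = sgn * mag * p[1] / r;
  f[2] = sgn * mag * p[2] / r;
  return 0.5 * G.wall_k * d_rad * d_rad;
}

// Tail wall at a point: the tail is a tube whose open lumen has radius
// tail_radius; its sheath occupies the annulus from tail_radius to
// tail_radius + 2 - thicker than the maximum FENE bond extension, so no
// single bond can span it and the chain can never hang over or thread
// through the sheath (a rope over any thin wall would snag its ridge). A
// point inside the sheath is pushed toward the nearer face: on the lumen
// side this is the retention force stiffness x (rho - tail_radius) toward
// the axis; force saturates at half-sigma penetration for stability. The
// tube extends down through the capsid wall shell so lumen and pore line
// up with no crevice at the junction.
static double tail_force_point(const double p[3], double f[3], const Geom &G) {
  f[0] = f[1] = f[2] = 0.0;
  if (!G.tail || G.tail_k <= 0.0) return 0.0;
  if (p[2] < G.R - G.wall_range || p[2] > G.R + G.tail_len) return 0.0;
  const double rho = std::sqrt(p[0] * p[0] + p[1] * p[1]);
  if (rho <= 1e-12) return 0.0;
  // lumen accessible to bead centers extends to the tube radius; the
  // retention ramp beyond it confines the strand without wedging it
  const double a_in = G.tail_rad;
  const double outer = G.tail_rad + 2.0;
  if (rho <= a_in || rho >= outer) return 0.0;
  const double mid = 0.5 * (a_in + outer);
  double depth, sgn;
  if (rho < mid) { depth = rho - a_in; sgn = -1.0; }  // push into the bore
  else           { depth = outer - rho; sgn = 1.0; }  // push off the tube
  double mag, U;
  if (depth < 0.5) {
    mag = G.tail_k * depth;
    U = 0.5 * G.tail_k * depth * depth;
  } else {  // force saturates; energy continues linearly
    mag = 0.5 * G.tail_k;
    U = 0.125 * G.tail_k + 0.5 * G.tail_k * (depth - 0.5);
  }
  // the sheath fades out over its last sigma below the tip: the rim is
  // soft (the supply rope may wrap it), and the strength gradient expels
  // anything pushed down into the sheath body
  const double zt = G.R + G.tail_len - p[2];  // depth below the tip
  if (zt < 1.0) {
    f[0] = sgn * mag * zt * p[0] / rho;
    f[1] = sgn * mag * zt * p[1] / rho;
    f[2] = U;  // -dU/dz with w = zt: pushes toward the open tip
    return U * zt;
  }
  f[0] = sgn * mag * p[0] / rho;
  f[1] = sgn * mag * p[1] / rho;
  return U;
}

// Wall + tail + motor force on a single bead; returns conservative energy
// contribution (motor excluded). Used by both the force loop and the
// R-visible per-bead geometry force accessors.
static double geometry_force_point(const double p[3], double f[3],
                                   const Geom &G, bool motor_on) {
  double U = 0.0;
  f[0] = f[1] = f[2] = 0.0;
  if (!G.enabled) return 0.0;

  const double rho2 = p[0] * p[0] + p[1] * p[1];
  const double r = std::sqrt(rho2 + p[2] * p[2]);

  double fw[3];
  U += wall_force_point(p, fw, G, G.pore_radius);
  f[0] += fw[0]; f[1] += fw[1]; f[2] += fw[2];

  double ft[3];
  U += tail_force_point(p, ft, G);
  f[0] += ft[0]; f[1] += ft[1]; f[2] += ft[2];

  // motor: constant force toward the capsid center on any bead within the
  // capture sphere at the pore mouth (non-conservative; no energy term).
  // With a tail the motor grips only the strand in the portal itself (beads
  // near the pore axis); beads loitering outside at the tube base are not
  // grabbed, which would wind the chain around the junction.
  if (motor_on && G.motor_F > 0.0 &&
      (!G.tail || rho2 < G.pore_radius * G.pore_radius)) {
    const double dx = p[0], dy = p[1], dz = p[2] - G.R;
    if (dx * dx + dy * dy + dz * dz < G.motor_capture * G.motor_capture &&
        r > 1e-12) {
      f[0] -= G.motor_F * p[0] / r;
      f[1] -= G.motor_F * p[1] / r;
      f[2] -= G.motor_F * p[2] / r;
    }
  }
  return U;
}

double bead_forces(const std::vector<double> &x, std::vector<double> &f, int N,
                   const PotParams &P, const Geom &G, bool motor_on,
                   int *err_bead) {
  double U = 0.0;
  std::fill(f.begin(), f.end(), 0.0);
  *err_bead = -1;

  const double r02 = P.fene_r0 * P.fene_r0;
  const double ljcut2 = P.lj_cut * P.lj_cut;
  const double eccut2 = P.elec_cut * P.elec_cut;
  const double sig2 = P.lj_sigma * P.lj_sigma;
  const double pair_cut2 =
      (P.charged && eccut2 > ljcut2) ? eccut2 : ljcut2;

  // FENE bonds between consecutive beads
  for (int i = 0; P.fene_k > 0.0 && i + 1 < N; ++i) {
    const double dx = x[3 * i] - x[3 * i + 3];
    const double dy = x[3 * i + 1] - x[3 * i + 4];
    const double dz = x[3 * i + 2] - x[3 * i + 5];
    const double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= r02) { *err_bead = i; return NA_REAL; }
    const double denom = 1.0 - r2 / r02;
    U += -0.5 * P.fene_k * r02 * std::log(denom);
    const double c = -P.fene_k / denom;  // attractive
    f[3 * i]     += c * dx;  f[3 * i + 1] += c * dy;  f[3 * i + 2] += c * dz;
    f[3 * i + 3] -= c * dx;  f[3 * i + 4] -= c * dy;  f[3 * i + 5] -= c * dz;
  }

  // nonbonded pairs: truncated-shifted LJ on all pairs (bonded included,
  // Kremer-Grest convention); screened electrostatics on pairs |i-j| > 1
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      const double dx = x[3 * i] - x[3 * j];
      const double dy = x[3 * i + 1] - x[3 * j + 1];
      const double dz = x[3 * i + 2] - x[3 * j + 2];
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= pair_cut2) continue;
      double cf = 0.0;  // force coefficient: F_i += cf * (r_i - r_j)
      if (r2 < ljcut2) {
        const double sr2 = sig2 / r2;
        const double sr6 = sr2 * sr2 * sr2;
        U += 4.0 * P.lj_eps * (sr6 * sr6 - sr6) + P.lj_shift;
        cf += 24.0 * P.lj_eps * (2.0 * sr6 * sr6 - sr6) / r2;
      }
      if (P.charged && j != i + 1 && r2 < eccut2) {
        const double r = std::sqrt(r2);
        const double pref = P.Tstar * P.A;
        const double ex = std::exp(-r / P.lambda_d);
        U += pref * ex / r;
        cf += pref * ex * (1.0 / r2 + 1.0 / (P.lambda_d * r)) / r;
      }
      if (cf != 0.0) {
        f[3 * i]     += cf * dx;  f[3 * i + 1] += cf * dy;  f[3 * i + 2] += cf * dz;
        f[3 * j]     -= cf * dx;  f[3 * j + 1] -= cf * dy;  f[3 * j + 2] -= cf * dz;
      }
    }
  }

  // bending rigidity: kappa * (1 - cos theta) per interior joint
  if (P.kappa > 0.0) {
    for (int j = 1; j + 1 < N; ++j) {
      const double b1x = x[3 * j] - x[3 * j - 3];
      const double b1y = x[3 * j + 1] - x[3 * j - 2];
      const double b1z = x[3 * j + 2] - x[3 * j - 1];
      const double b2x = x[3 * j + 3] - x[3 * j];
      const double b2y = x[3 * j + 4] - x[3 * j + 1];
      const double b2z = x[3 * j + 5] - x[3 * j + 2];
      const double n1 = std::sqrt(b1x * b1x + b1y * b1y + b1z * b1z);
      const double n2 = std::sqrt(b2x * b2x + b2y * b2y + b2z * b2z);
      if (n1 < 1e-12 || n2 < 1e-12) { *err_bead = j; return NA_REAL; }
      const double inv12 = 1.0 / (n1 * n2);
      const double ct = (b1x * b2x + b1y * b2y + b1z * b2z) * inv12;
      U += P.kappa * (1.0 - ct);
      // dcos/db1 = b2/(n1 n2) - ct b1/n1^2 ; dcos/db2 = b1/(n1 n2) - ct b2/n2^2
      const double g1x = b2x * inv12 - ct * b1x / (n1 * n1);
      const double g1y = b2y * inv12 - ct * b1y / (n1 * n1);
      const double g1z = b2z * inv12 - ct * b1z / (n1 * n1);
      const double g2x = b1x * inv12 - ct * b2x / (n2 * n2);
      const double g2y = b1y * inv12 - ct * b2y / (n2 * n2);
      const double g2z = b1z * inv12 - ct * b2z / (n2 * n2);
      // F_{j-1} = -kappa * dcos/db1 ; F_{j+1} = +kappa * dcos/db2
      f[3 * j - 3] -= P.kappa * g1x;
      f[3 * j - 2] -= P.kappa * g1y;
      f[3 * j - 1] -= P.kappa * g1z;
      f[3 * j + 3] += P.kappa * g2x;
      f[3 * j + 4] += P.kappa * g2y;
      f[3 * j + 5] += P.kappa * g2z;
      f[3 * j]     += P.kappa * (g1x - g2x);
      f[3 * j + 1] += P.kappa * (g1y - g2y);
      f[3 * j + 2] += P.kappa * (g1z - g2z);
    }
  }

  // capsid wall, tail retention, motor
  if (G.enabled) {
    double p[3], fg[3];
    for (int i = 0; i < N; ++i) {
      p[0] = x[3 * i]; p[1] = x[3 * i + 1]; p[2] = x[3 * i + 2];
      U += geometry_force_point(p, fg, G, motor_on);
      f[3 * i] += fg[0]; f[3 * i + 1] += fg[1]; f[3 * i + 2] += fg[2];
    }
    // bonds carry excluded volume against the wall: the wall repulsion is
    // sampled at three interior points of every bond (t = 1/4, 1/2, 3/4), so
    // the chain is a tube that cannot thread or slide through the shell away
    // from the pore. The suppression channel for these samples is a wider
    // vestibule around the pore so a bond spanning the waist feeds without
    // strain. Forces are distributed to the endpoints with linear weights.
    const double vestibule = G.tail ? 0.45 : G.pore_radius + 0.6;
    static const double tfrac[5] = {1.0 / 6, 2.0 / 6, 3.0 / 6, 4.0 / 6,
                                    5.0 / 6};
    for (int i = 0; i + 1 < N; ++i) {
      for (int k = 0; k < 5; ++k) {
        const double t = tfrac[k];
        p[0] = (1.0 - t) * x[3 * i]     + t * x[3 * i + 3];
        p[1] = (1.0 - t) * x[3 * i + 1] + t * x[3 * i + 4];
        p[2] = (1.0 - t) * x[3 * i + 2] + t * x[3 * i + 5];
        U += wall_force_point(p, fg, G, vestibule);
        double fgt[3];
        U += tail_force_point(p, fgt, G);
        fg[0] += fgt[0]; fg[1] += fgt[1]; fg[2] += fgt[2];
        f[3 * i]     += (1.0 - t) * fg[0];
        f[3 * i + 1] += (1.0 - t) * fg[1];
        f[3 * i + 2] += (1.0 - t) * fg[2];
        f[3 * i + 3] += t * fg[0];
        f[3 * i + 4] += t * fg[1];
        f[3 * i + 5] += t * fg[2];
      }
    }
  }
  return U;
}

// [[Rcpp::export]]
List cpp_bead_forces(NumericMatrix pos, List pot, List geom, double Tstar,
                     bool motor_on) {
  const int N = pos.nrow();
  PotParams P = pot_from_list(pot, Tstar);
  Geom G = geom_from_list(geom);
  std::vector<double> x(3 * N), f(3 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = pos(i, k);
  int err;
  double U = bead_forces(x, f, N, P, G, motor_on, &err);
  if (err >= 0)
    stop("force evaluation failed at bead %d (overstretched bond or degenerate geometry)",
         err + 1);
  NumericMatrix F(N, 3);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) F(i, k) = f[3 * i + k];
  return List::create(_["forces"] = F, _["energy"] = U);
}

// [[Rcpp::export]]
IntegerVector cpp_classify(NumericMatrix pos, List geom) {
  Geom G = geom_from_list(geom);
  const int N = pos.nrow();
  IntegerVector out(N);
  for (int i = 0; i < N; ++i)
    out[i] = classify_point(pos(i, 0), pos(i, 1), pos(i, 2), G);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_geometry_force(NumericVector pos, List geom, bool motor_on) {
  Geom G = geom_from_list(geom);
  double p[3] = {pos[0], pos[1], pos[2]};
  double f[3];
  double U = geometry_force_point(p, f, G, motor_on);
  NumericVector out = NumericVector::create(f[0], f[1], f[2]);
  out.attr("energy") = U;
  return out;
}
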