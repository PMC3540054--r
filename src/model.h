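#ifndef PHAGEPACK_MODEL_H
#define PHAGEPACK_MODEL_H

#include <Rcpp.h>
#include <vector>

// Parameter bundles mirrored from the R-side interaction_params() and
// capsid_assembly() lists. All quantities are in reduced units
// (sigma = epsilon = bead mass = k_B = 1).

struct PotParams {
  double fene_k;    // FENE spring strength, epsilon/sigma^2
  double fene_r0;   // maximum bond extension, sigma
  double lj_eps;    // excluded-volume energy scale
  double lj_sigma;  // bead diameter
  double lj_cut;    // excluded-volume cutoff (2^(1/6) sigma: WCA)
  double lj_shift;  // energy shift so U(cutoff) = 0 (precomputed)
  double kappa;     // bending constant, epsilon per joint
  bool   charged;
  double A;         // electrostatic prefactor (reduced l_B * Z^2), length units
  double lambda_d;  // Debye screening length, sigma
  double elec_cut;  // electrostatic cutoff, sigma
  double Tstar;     // reduced temperature (electrostatics scale linearly in T*)
};

struct Geom {
  bool   enabled;       // false: free chain, no capsid/motor forces
  double R;             // capsid radius
  double pore_radius;   // pore channel radius (< sigma: single-file)
  double wall_k;        // wall repulsion stiffness
  double wall_range;    // half-thickness of the repulsive wall shell
  bool   tail;
  double tail_len;      // tail cylinder length, from the sphere surface
  double tail_rad;      // tail cylinder radius
  double tail_k;        // tail retention stiffness
  double motor_F;       // constant feeding force magnitude
  double motor_capture; // radius of the capture sphere at the pore mouth
};

PotParams pot_from_list(const Rcpp::List &L, double Tstar);
Geom geom_from_list(const Rcpp::List &L);

// Total conservative force on every bead (+ motor when motor_on).
// x is 3N (bead-major: x0,y0,z0,x1,...). Returns potential energy of the
// conservative terms; the motor force is non-conservative and excluded from
// the energy. On an overstretched bond, *err_bead is set and NaN returned.
double bead_forces(const std::vector<double> &x, std::vector<double> &f, int N,
                   const PotParams &P, const Geom &G, bool motor_on,
                   int *err_bead);

// Region codes used by classification and occupancy counts.
enum Region { REG_INSIDE = 0, REG_PORE = 1, REG_TAIL = 2, REG_OUTSIDE = 3 };
int classify_point(double px, double py, double pz, const Geom &G);

#endif
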