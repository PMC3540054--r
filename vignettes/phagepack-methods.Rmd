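---
title: "Model and methods: coarse-grained packaging and ejection of a viral genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: coarse-grained packaging and ejection of a viral genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phagepack)
```

# The physical model

`phagepack` simulates the packaging and ejection of a semiflexible polymer -
a coarse-grained phage genome - through the single pore of a rigid spherical
capsid, driven by a constant-force motor and immersed in a particle-based
(SRD/MPCD) solvent. Everything is in reduced units: bead diameter
$\sigma = 1$, energy $\epsilon = 1$, bead mass $m = 1$, $k_B = 1$, time unit
$\tau = \sigma\sqrt{m/\epsilon}$. The physical anchors are: one reduced
force unit = 1.6 pN (so the default motor force of 80 units is 128 pN), the
capsid radius $3.02\,\sigma$ = 7.5 nm (so $\sigma \approx 2.48$ nm), and
$T^{*}=1$ at 37 °C, making $\epsilon = k_BT_{37}\approx 4.3$ pN nm. These
three anchors are mutually consistent only to a few percent
($\epsilon/\sigma = 1.72$ pN, not 1.6 pN); the package stores each anchor as
its own constant and never derives one from another, so every printed
conversion matches its stated value exactly.

## Chain energetics

The genome is a Kremer-Grest bead-spring chain of $N$ beads (default 100):

* **FENE bonds** between consecutive beads,
  $U(r) = -\tfrac12 k R_0^2 \ln\!\left[1-(r/R_0)^2\right]$ with
  $k = 30\,\epsilon/\sigma^2$, $R_0 = 1.5\,\sigma$. The divergence at $R_0$
  prevents bond breaking and chain crossing.
* **Excluded volume**: truncated-shifted Lennard-Jones on *all* bead pairs,
  bonded pairs included, cut at $2^{1/6}\sigma$ (WCA) - purely repulsive,
  i.e. good-solvent conditions. Together with the FENE spring this puts the
  equilibrium bond length at $\approx 0.97\,\sigma$.
* **Bending rigidity**: $U = \kappa\,(1-\cos\theta)$ per interior joint.
  $\kappa$ is not chosen a priori: it is *calibrated* so the free chain's
  persistence length is $10\,\sigma$ (below). The calibrated default is
  $\kappa = 10.18\,\epsilon$.
* **Screened electrostatics** (optional, `charged = TRUE`): a Debye-Hückel
  repulsion $U(r) = T^{*} A\, e^{-r/\lambda_D}/r$ between nonbonded pairs,
  with $\lambda_D = 0.75\,\sigma$ (1.9 nm, roughly 100 mM monovalent salt)
  and cutoff $4\lambda_D = 3\,\sigma$. The energy is written with an
  explicit factor $T^{*}$: electrostatic forces strengthen on heating and
  weaken on cooling, which is the coupling that drives all of the
  temperature asymmetries of the charged chain. The prefactor $A$
  (effectively Bjerrum length x squared charge per bead) is calibrated, not
  assumed (below). The Bjerrum length of water at 37 °C,
  $l_B = e^2/(4\pi\varepsilon_0\varepsilon_r k_BT) \approx 0.7$ nm, is
  computed from physical constants by `bjerrum_length_nm()`.

## Capsid, pore, funnel, tail, motor

The capsid is a rigid sphere of radius $R = 3.02\,\sigma$ centred at the
origin, permeable to the solvent. Beads are repelled from the wall on both
sides within a shell of half-thickness $0.5\,\sigma$ about the surface; the
force is linear in the penetration depth with stiffness
$800\,\epsilon/\sigma^2$. Two modelling requirements fix this number and
the two structural choices described next; all three emerged from pilot
runs in which softer or thinner walls let the driven chain do unphysical
things:

1. **The wall must beat the motor.** The maximum wall force
   (stiffness x range = 400) must exceed the feeding force (80), otherwise
   beads are simply pushed through the shell beside the pore.
2. **The chain is a tube, not a string of points.** The wall repulsion is
   evaluated at each bead centre *and* at five interior points of every
   bond. Without this, a bond of length $\approx\sigma$ straddles the
   1-$\sigma$-thick shell almost freely and the chain can thread and slide
   through the wall anywhere, producing absorbing jams ("rope over the
   rim") far from the pore.
3. **The pore mouth is a funnel.** The pore is a cylindrical channel of
   radius $0.6\,\sigma$ (one bead cross-section, with clearance) through
   the upper hemisphere, opening into a cone of unit slope above the
   surface. Within the wall shell the repulsion is
   stiffness x (distance to the nearest free region), directed toward it:
   a bead pressed onto the mouth therefore slides *into* the waist instead
   of rattling on a hard rim, much as the funnel-shaped portal vestibule of
   a real phage guides the genome. For the bond interior points the
   suppression channel is widened by $0.6\,\sigma$ so the bond spanning the
   waist feeds without strain.

The **motor** is a constant force of 80 units directed from the bead toward
the capsid centre, applied to every bead within $1.25\,\sigma$ of the pore
mouth - large enough that the funnel mouth contains no drive-free corridor
through which the chain could retract. In the protocol integrator the
drive carries two stall conditions, as real packaging motors do: it does no
work on a bead already translocating inward faster than $1\,\sigma/\tau$,
and it does not pull when the backbone bond ahead of the grabbed bead is
already tauter than the motor's own force (bond beyond $1.16\,\sigma$,
where the FENE tension reaches $\approx 85$). Without these gates the
80-unit force outruns the solvent friction between collision steps, the
chain "fountains" ballistically, and its recoil can eject everything. With
a tail the motor grips only the strand inside the portal (beads within the
pore radius of the axis). The exposed `motor_force()` and `total_forces()`
keep the plain position-only constant force. Ejection mode is the same
model with the feeding force identically zero.

The optional **tail** is a tube of length $6\,\sigma$ on the pore axis
whose open lumen has radius $0.7\,\sigma$, wrapped in a sheath two bead
diameters thick. A bead entering the sheath from the lumen is pulled back
toward the axis with force $800\,(\rho - 0.7)$, saturating at half-sigma
penetration; from the outside it is repelled off the tube by the mirror
law. Three geometric properties took several design iterations to get
right and are essential: (i) the sheath is *thicker than the maximum bond
extension*, so no bond can span it and the chain can neither thread it nor
hang over it like a rope on a wall (thin-walled tubes deadlocked the
driven chain reproducibly); (ii) the sheath softens linearly over its last
sigma at the open tip, so the supply rope can wrap the rim without being
cut into it and anything pushed down into the sheath is expelled back
toward the opening; (iii) the tube extends down through the capsid wall
shell so lumen and pore line up with no crevice at the junction.

All geometry forces act on polymer beads only; solvent particles pass
through the capsid freely.

## Solvent and thermostat

The solvent is stochastic rotation dynamics (multi-particle collision
dynamics): point particles of mass $1/\gamma$ stream ballistically and, at
discrete intervals, have their velocities rotated about their collision
cell's centre-of-mass velocity by a fixed angle about a random axis. Beads
participate in the collision as ordinary cell members, which transfers
momentum between chain and fluid and transmits hydrodynamic interactions.
Defaults (standard for the method, all configurable): cell size
$a = 1\,\sigma$, rotation angle 130°, mean density $\gamma = 5$ particles
per cell, one collision every 10 MD steps ($0.05\,\tau$ - chosen so the
motor's free-flight velocity gain between collisions stays of order the
thermal speed), random grid shifting for Galilean invariance, periodic box
of edge $16\,\sigma$ for full-scale runs.

The rotation conserves per-cell momentum and kinetic energy exactly, so
plain SRD is *not* a thermostat. In a finite box the motor's work
(~$80\,\epsilon$ per packed bead) would heat the bath appreciably, so the
package enables a cell-level Maxwell-Boltzmann rescaling (MBS) thermostat:
on every second collision step each cell's relative-velocity kinetic energy
is rescaled to a draw from the canonical Gamma distribution. This conserves
per-cell momentum, samples the canonical ensemble, and holds the bath at
the target $T^{*}$ within 2%. During active feeding the chain itself still
runs warm (by $\sim0.2$ in $T^{*}$) - the motor pumps energy in faster than
the bath drains it; this is a property of the driven stage, reported by the
run records as `mean_T`.

Switching **hydrodynamics off** replaces every solvent velocity by a fresh
Maxwell-Boltzmann draw after each collision step. Single-particle statics
(bond lengths, persistence length, any equilibrium average) are unchanged;
solvent velocity correlations - and with them momentum transport between
distant beads - are destroyed.

## Protocols

* **Packing**: one bead is placed just inside the pore, the next few are
  threaded single-file out through the pore (and tail), and the rest grown
  as a clash-free persistent coil outside. After equilibration with the
  inside bead pinned, the motor switches on and the run ends when every
  bead centre is inside the sphere, or when the `max_steps` budget expires
  (status `timeout`).
* **Ejection**: from a fully packed state the chain is slid along its own
  contour so the terminal bead sits just past the capsid wall - outside
  the pore (tailless) or in the tube lumen just above it (tailed), so the
  capsid holds $N-1$ beads either way and, with a tail, the entire genome
  still has to transit the full tube. After equilibration with that bead
  pinned, the motor stays off and the run ends when no bead centre remains
  in capsid, pore or tail. Thermal re-entry through the open pore is
  allowed; transiently re-packed beads are part of the dynamics.
* **Packed states** can come from an actual packing run
  (`run_pack_then_eject()`, the sequential protocol) or from
  `build_packed_state()`: a deterministic winding of the chain over
  concentric spherical shells (shell spacing = bond length, polar caps
  sized so that no two sites approach closer than $0.92\,\sigma$), with the
  last-packed bead at the pole under the pore. The constructed state makes
  ejection ensembles affordable and is also the only way to seed ejection
  at conditions where packing itself stalls (charged chain at
  $T^{*} = 1.2$).

Every replicate derives independent random streams from the master seed;
identical (configuration, seed, build) triples reproduce trajectories
bit for bit.

# Calibrated parameters

## Bending rigidity

`calibrate_bending_rigidity()` bisects on $\kappa$; each trial measures the
persistence length of a free 100-bead chain by fitting
$\langle\cos\theta(s)\rangle = e^{-s\,b/l_p}$ over contour separations
$s = 1..15$ bonds. Numerical choices that matter:

* Sampling uses Langevin (BAOAB) dynamics - equilibrium conformational
  statistics do not depend on the dynamics, so the SRD machinery is not
  needed here. Conformations are split over many short *independent*
  trajectories (default 40), each initialized from an exact ideal
  worm-like-chain Boltzmann draw (inverse-CDF per joint) with a
  self-avoidance guard; a straight-rod start would need the slowest global
  bending modes to relax and biases the estimate upward.
* The log-linear fit is weighted by $C(s)^2$: sampling noise is roughly
  homoscedastic in $C$, so on the log scale the large-$s$ points are the
  noisiest. The weighting also de-emphasizes the slowly-decaying
  self-avoidance tail of the correlation, which is not exponential.
* Bisection trials share common random numbers (the same three seed
  streams at every $\kappa$), which makes the measured $l_p(\kappa)$
  monotone along the search path; the three streams are averaged to keep
  any single stream's bias small.

The calibrated default $\kappa = 10.18\,\epsilon$ is close to the
first-order worm-like-chain estimate $\kappa \approx l_p T^{*}/b = 10.3$.
Repeated independent measurements at this $\kappa$ give
$l_p = 9.9 \pm 0.5\,\sigma$.

## Electrostatic prefactor

The printed value of the charge prefactor is not available, but the study
it reproduces states an operational criterion: the charged, tailless chain
packs fully at $T^{*} = 1.0$ and fails to pack fully at $T^{*} = 1.2$
(electrostatic repulsion grows with $T^{*}$). Pilot grids over
$A \in \{4\ldots64\}$ at the scaled reference conditions (below) show the
transition only opens near $A = 64$: there, packing completes at
$T^{*}=1.0$ in every pilot replicate while at $T^{*}=1.2$ most replicates
stall within a few beads of completion and time out. $A = 64$ is the
package default. In physical terms this corresponds to a strongly charged
chain (DH contact energy $\approx 17\,\epsilon\,T^{*}$ at
$r = \sigma$), consistent with the need for a 128 pN motor.

# Scaled-down study conditions

Full-size ensembles (100 beads, $16\,\sigma$ box, 100 replicates, up to
$2\times10^6$ MD steps each) are cluster-scale. The package's test and
acceptance experiments run at a reference desk scale, exposed as
`scaled_config()`: $N = 40$ beads, box $12\,\sigma$, 10 replicates,
$4\times10^5$-step budgets - and, crucially, a capsid radius scaled as
$R = 3.02\,(N/100)^{1/3} = 2.23\,\sigma$. The confinement physics
(crowding, electrostatic resistance, bending stress of the confined chain)
is controlled by the packing fraction; keeping it at the full-scale value
of $\approx 0.45$ keeps the scaled system in the same regime. Without this
scaling ($N = 40$ in the full-size sphere, fraction 0.18) packing meets no
resistance and every temperature and charge effect disappears.

What the scaled ensembles do show: the *orderings* - ejection slower when
cold; charged packing blocked when hot; tail helps packing and hinders
ejection; hydrodynamics damping the neutral packing temperature gap; more
nematic order with a tail. What they cannot show: the full-scale absolute
time constants, the shapes of full 100-replicate distributions, or
finite-size-free hydrodynamics (a $12\,\sigma$ periodic box is small for
long-range flow fields).

## Event statistics and trapped states

Replicates that exhaust the step budget are never dropped: the event-time
distribution carries an explicit terminal bin, and summary means are
reported both over completed runs and with timeouts censored at the
budget. The two answer different questions. Censored means measure how
much of the ensemble is trapped; completed-run means measure how fast the
polymers that do eject move. At the scaled conditions a large fraction of
*charged* tailless ejections stalls half-way - the ejected charged coil
cannot disperse in the small periodic box and its back-pressure balances
the capsid drive, increasingly so at higher $T^{*}$ where electrostatics
are stronger. The temperature ordering of ejection speed is therefore read
from completed runs, with the stall fraction reported alongside.

# Degenerate inputs and numerical edges

* Overstretched bonds ($r \ge R_0$) and zero-length bonds raise errors
  naming the step and bead rather than propagating NaNs.
* The wall/funnel force field is piecewise smooth; the seams between the
  radial branch and the channel branch are the model's documented
  pore-edge discontinuities. All other forces are continuous; analytic
  forces match central finite differences of the energy to $10^{-5}$
  relative everywhere away from the seams.
* Velocity-Verlet at $\delta t = 0.005\,\tau$ is stable for the stiffest
  terms (wall stiffness 800 gives $\delta t\,\omega \approx 0.14$); NVE
  energy drift of an isolated chain is $< 10^{-4}$ relative over $10^4$
  steps (secular drift of block-averaged energy; the symplectic
  oscillation amplitude is $\sim10^{-4}$).
* A rigid-rod conformation set yields a non-decaying bond correlation; the
  persistence-length estimator returns `Inf` with a flag instead of a
  number.
* All-timeout ensembles are valid: the event-time distribution becomes a
  pure spike at the budget edge, which is exactly the phenomenology of
  tail-trapped charged ejection.

# Known limitations

* The funnel mouth, bond-interior wall sampling, and capture radius are
  modelling choices made so that the driven chain can neither cross nor
  permanently jam against the wall; they are documented here rather than
  derived from the source study, which does not print its wall law.
* The chain heats above the nominal $T^{*}$ while the motor feeds; the
  bath, and the chain between feeding events, stay at target.
* Bead-bead interactions are not minimum-imaged (the chain is a single
  molecule, tracked in unwrapped coordinates); solvent coupling wraps bead
  positions into the periodic box. With the recommended box sizes the coil
  never spans half the box.
* `build_packed_state()` requires the shell winding to fit: it supports up
  to roughly 70 beads at full scale and 40 at the scaled radius; beyond
  that, generate packed states by running the packing protocol.
* Hydrodynamic screening by the periodic images is significant at box edge
  $12\,\sigma$; hydrodynamics-on/off *contrasts* remain meaningful because
  both arms share the geometry.
* Two full-scale contrasts are at or below the desk scale's resolution:
  the tail slows (neutral) ejection here by a factor of only ~1.2 rather
  than ~2 - the ejected coil crowded near the tube tip in the small box
  pulls the remaining chain through the frictionless lumen, cancelling
  most of the entropic slowdown - and the nematic-order contrast between
  packed charged chains with and without a tail is within the metric's
  noise at $N = 40$ (~0.20 both arms). Both are expected to sharpen with
  box size and chain length.
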