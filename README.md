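# phagepack

Coarse-grained simulation of viral genome packaging and ejection.

Bacteriophages pack their genome into a protein capsid against enormous
bending and electrostatic resistance, and later eject it into a host cell.
`phagepack` implements a minimal physical model of that cycle for studying
how **temperature**, **backbone charge** and a **capsid tail** change the
kinetics of both processes. It is aimed at polymer/biophysics researchers
who want a self-contained, scriptable engine for translocation ensembles
rather than a general-purpose MD code.

## The model

The genome is a Kremer–Grest bead–spring polymer of `N` beads (diameter
σ, the reduced length unit):

- FENE bonds: `U(r) = -½ k R₀² ln[1-(r/R₀)²]`, `k = 30 ε/σ²`, `R₀ = 1.5 σ`;
- excluded volume: WCA (Lennard-Jones truncated at `2^{1/6} σ` and shifted)
  on all pairs — good-solvent conditions, equilibrium bond length ≈ 0.97 σ;
- bending rigidity `κ (1 - cos θ)` per joint, with κ **calibrated** so the
  free chain's persistence length is 10 σ (`calibrate_bending_rigidity()`);
- optional Debye–Hückel electrostatics `U = T* A e^{-r/λ_D}/r` with
  `λ_D = 0.75 σ` (1.9 nm ≈ 100 mM salt); the explicit `T*` factor makes
  electrostatic forces grow with temperature.

The capsid is a rigid sphere of radius 3.02 σ (7.5 nm) with a single-bead
pore that opens into a funnel-shaped mouth; an optional tail (a tube of
length 6 σ, lumen radius 0.7 σ) attaches to the pore. A motor applies a
constant force of 80 reduced units (128 pN; 1 unit = 1.6 pN) toward the
capsid center to beads near the pore. The solvent is stochastic rotation
dynamics (SRD/MPCD) with the polymer beads participating in the cell-wise
collisions; switching `hydrodynamics = FALSE` resamples solvent velocities
each collision step, destroying hydrodynamic correlations while leaving all
equilibrium statistics unchanged. Reduced temperature `T* = 1` corresponds
to 37 °C (`ε = k_B T₃₇ ≈ 4.3 pN nm`).

The methods vignette (`vignettes/phagepack-methods.Rmd`) documents every
parameter, the calibrations, and the design decisions in detail.

## Worked example

A small packing ensemble at the desk-scale reference conditions
(`scaled_config()`: 40 beads, capsid radius scaled to keep the full-scale
packing fraction of ≈ 0.45, 12 σ box):

```r
library(phagepack)

cfg <- scaled_config(n_replicates = 4)
ens <- run_ensemble(cfg, "packing", seed = 1)
ens
#> ensemble_result: packing, 4 replicate(s), completion fraction 1.00
#>   completed event time: mean 2.3e+04, median 2.46e+04 MD steps (n = 4)

event_time_distribution(ens)
#> event_time_distribution: 4 run(s), 0 timeout(s) at budget 400000
#>   completed: mean 2.302e+04, median 2.464e+04 MD steps
#>   censored-at-budget mean: 2.302e+04 MD steps
```

All four replicates packed completely (completion fraction 1.00), taking on
average ≈ 23,000 MD steps (≈ 115 τ) from motor switch-on to the last bead
entering the capsid. With `tail_present = TRUE` the same ensemble completes
about twice as fast; with `charged = TRUE` at `reduced_temperature = 1.2`
most replicates stall near-full and time out — the two headline effects of
the study this package reproduces.

Unit conversions and the derived geometry:

```r
to_physical(80, "force")        # 128  (pN)
to_physical(0.75, "length")     # 1.86 (nm, prints as ~1.9)
bjerrum_length_nm()             # 0.673 (nm, water at 37 C)
packing_fraction(100, 1, 3.02)  # 0.454
```

Single runs are available as `run_packing()` / `run_ejection()` (or
`run_pack_then_eject()` for the sequential protocol), and trajectories,
time series and manifests are written with `write_trajectory()` (XYZ),
`write_timeseries()` (CSV) and `write_run_manifest()` (JSON). A thin
command-line driver lives at `inst/cli/phagepack.R`:

```sh
Rscript inst/cli/phagepack.R pack --config my.yml --seed 7 --out-dir out/
```

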