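---
title: "Coarse-grained DPD of asymmetric lipid membranes under shear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained DPD of asymmetric lipid membranes under shear}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpdlipid)
library(dplyr)
```

## The model

`dpdlipid` simulates two amphiphile species in explicit coarse-grained
water with dissipative particle dynamics (DPD). A bead stands for a group
of atoms or water molecules; beads interact through three pairwise forces
acting along the connecting line within a cutoff `rc`:

* a soft conservative repulsion `F^C = a_ij (1 - r/rc) r_hat`, whose
  amplitude `a_ij` plays the role of a Flory–Huggins-like immiscibility;
* a dissipative drag `F^D = -gamma w(r)^2 (r_hat . v_ij) r_hat`;
* a random kick `F^R = sigma w(r) zeta_ij dt^{-1/2} r_hat`.

The last two form a momentum-conserving (Galilean-invariant) thermostat;
the fluctuation–dissipation relation `sigma^2 = 2 gamma kBT` ties the
noise amplitude to the friction, and `dpd_params()` enforces it: with the
standard `gamma = 4.5` at `kBT = 1`, `sigma = 3` exactly. All quantities
are in reduced units — lengths in `rc`, energies in `kBT`, masses in the
bead mass, times in `tau = rc sqrt(m/kBT)`. The physical mapping
(`unit_system()`) takes a bead volume of 0.03 nm^3 at number density
`rho = 3`, so `rc ~ 0.5 nm` and `tau = 1.88 ns`; with the timestep
`dt = 0.01 tau` one step is 0.0188 ns (`physical_time()`).

Two lipid architectures are built by `build_lipid_type1()` and
`build_lipid_type2()`. Both have 3 head beads; type 1 carries one tail,
type 2 two tails attached to the last head bead. Consecutive beads are
bonded harmonically (`ks = 120`, `rs = 0.7 rc`); triples inside the head
or a tail are kept straight (`ktheta = 6`, `theta0 = pi`), and the
two-tail junction carries softer bending terms at `theta0 = 2 pi / 3`
(`ktheta = 3` on head–head–tail, `ktheta = 4.5` on head–tail–tail, one
pair of terms per tail, each tail coupled to the head independently).
Two choices here were genuinely open and are worth stating:

* For type 1 the head–tail junction triples are not prescribed by the
  junction rules above; we apply the straight-backbone term across them
  (configurable off via `junction_angles = FALSE`) so the whole molecule
  is rod-like at equilibrium — consistent with the initial shape factor
  of 1.0 that the dynamics should start from.
* The interaction matrix sentence "`a_ii = 25`, `a_ij = 100`" read
  literally over the five species would repel head groups from water,
  which contradicts the hydrophilic role head beads play in the observed
  structures. The default `interaction_table("amphiphilic")` therefore
  groups species into a hydrophilic class (water + both heads) and a
  hydrophobic class (both tails) with 25 within and 100 across classes —
  the standard lipid-DPD convention. The literal matrix is retained as
  `interaction_table("literal")` for audit; it does not self-assemble
  bilayers, and all self-assembly tests use the class form.

## Integration and the random stream

`run_dpd()` advances the system with the modified velocity-Verlet scheme:
position update with the half-`dt^2` force term, a predicted velocity
`v + lambda dt f`, force recomputation at the new positions using the
predicted velocity in the drag term, then the trapezoidal velocity
correction. The mixing parameter `lambda` is never printed alongside the
scheme in the source material; we default to 0.5, which reduces to the
standard velocity-Verlet form, and expose it in `dpd_params()`.

The pair noise `zeta_ij` is drawn from a uniform distribution with unit
variance (a Gaussian is available via `gaussian = TRUE`). It is generated
counter-based: a hash of `(seed, step, i, j)` with `i < j`, so
`zeta_ij = zeta_ji` holds exactly, Newton's third law is satisfied by the
random force, and a run is bitwise reproducible regardless of pair
iteration order. Pair search uses a cell list (edge >= `rc`, half-shell
iteration), falling back to all-pairs for boxes under three cells per
axis; the enumerated pair set is property-tested against brute force.

Degenerate geometry is handled deterministically: coincident bonded beads
are separated by a fixed epsilon along x, and the bending gradient clamps
`sin(theta)` at 1e-8 near 0 and pi.

## Synthetic systems

`random_initial_configuration()` reproduces the production setup: each
lipid is built at its exact equilibrium internal geometry (bonds at `rs`,
every bending term at its `theta0`; the two tails splayed symmetrically at
120 degrees in a random plane), dropped at a uniform random position and
orientation, and water fills the box to `round(rho V)` beads. Overlaps
are not rejected — DPD potentials are soft and relax them within a few
steps, which is standard practice and keeps setup O(N). Velocities are
Maxwell–Boltzmann at `kBT`, shifted to exactly zero net momentum.
Defaults are the production conditions: cubic box of side 30 `rc`,
`n1 = n2 = 600` lipids, 3 head beads, 10-bead tails, 200,000 steps.

`preassembled_bilayer()` is a fast-equilibration fixture: type-2 lipids
as the upper leaflet, type-1 as the lower, chains straight along z with
tails meeting at the mid-plane and water outside. It skips the
self-assembly stage, which at full scale takes most of the run.
`synthetic_geometry()` builds idealized slab / cylinder / sphere bead
arrangements as classifier fixtures. What these generators do *not*
emulate is as important: they contain no pre-formed defects, no
composition gradients within a leaflet, and the bilayer fixture's type-2
tails are straight rather than splayed, so tests passing on them
demonstrate the machinery, not the full self-assembly pathway — that
pathway is exercised (at reduced scale) by `phase_sweep()` and (at
production scale) by `inst/scripts/long_runs.R`.

## Shear protocol

Shear is imposed by the reverse non-equilibrium (momentum-swap) method:
the box is cut into `n_slabs` z-slabs (default 20), and every `W` steps
the bead with the most negative `px` in slab 0 swaps x-velocities with
the bead with the most positive `px` in the mid slab. Equal masses make
this a pure momentum exchange: total momentum and kinetic energy are
conserved to machine precision at every event (property-tested). The
driven slabs sit at z = 0 and z = Lz/2 — the text's "z = 0 and z = Lz"
coincide under periodicity, and the half-box geometry is what produces
the two linear branches of the velocity profile. One pair is exchanged
per event; `W = 6` and `W = 1` are the weak and strong drive settings.

The accumulated swapped momentum gives the imposed flux
`j = px / (2 t Lx Ly)` (`momentum_flux()`), and `velocity_profile()`
fits the two branches (excluding the driven slabs) by least squares; the
shear rate is the mean absolute branch slope and the viscosity
`eta = j / shear_rate`. On a pure water box this machinery measures
`eta ~ 1.0` in reduced units at `rho = 3`, `a = 25` — the expected range
for standard DPD water — and flux, slope and viscosity are mutually
consistent by construction and tested for Newtonian consistency across
drive strengths.

## Observables

* `density_profile()`: frame-averaged number density per species per
  axis bin; integrates back to the bead count (tested to +-0.5 beads).
* `order_parameter()`: `P2 = (3 cos^2 theta - 1)/2` of the first-to-last
  head-bead vector against an axis, averaged per head-centroid bin.
  We report the signed P2 (1 parallel, -0.5 perpendicular, 0 isotropic)
  and do not adopt an absolute-value convention for perpendicular
  chains; binning uses the head-block centroid (configurable by axis).
* `gyration_tensor()` / `shape_factor()`: per-chain second-moment tensor
  about the centre of mass after minimum-image unwrapping along the bond
  graph; eigenvalues sorted descending; `delta` in [0, 1] from 0
  (sphere) to 1 (rod). Reported components `Rgxx` etc. are square roots
  of the diagonal entries, i.e. lengths — the natural reading of
  component time-series plotted in length units.
* `pressure_profile()` / `tension_profile()`: slab-resolved diagonal
  pressure components. Kinetic terms go to the bead's slab; each pair
  virial term is spread over the slabs crossed by the minimum-image
  segment (Irving–Kirkwood contour), and three-body bending terms are
  decomposed into their two vertex-anchored segments. This makes the
  volume-weighted slab mean equal the global virial *exactly* (tested at
  1e-10, and against an independent brute-force virial at 1e-6). The
  virial includes conservative pair, bond and angle forces only: the
  thermostat's dissipative and random contributions time-average to the
  ideal part already counted kinetically and would only add noise.
  Tension is `sigma_z = pzz - (pxx + pyy)/2` per slab.

## Phase classification

The structures of interest — membrane, tube, vesicle — differ in how
their hydrophobic core spans the periodic box. `classify_structure()`
clusters tail beads at link distance `rc` (the interaction range) and
tests the largest cluster for percolation by tracking periodic-image
offsets during the cluster walk: spanning two or more axes is a
membrane, exactly one a tube. A non-spanning cluster is a vesicle when
its far-shell beads cover >= 85% of 26 direction sectors around the
cluster centre (a closed-surface test; compact micelles pass it too and
are deliberately labelled vesicles — the evidence list retains the
enclosed-water flag for the distinction). The rule is deterministic and
invariant under periodic translation and axis permutation, and exact on
randomized synthetic fixtures.

`phase_sweep()` drives reduced-scale tail-length grids (default
`L = 15 rc`, 150 + 150 lipids, 50,000 steps — an approximation chosen
for affordability, not the production scale) over multiple seeds,
recording per-seed labels and final potential energies; `modal_phase()`
summarises cells. The production protocol of choosing the minimum-energy
structure among several initial states is approximated by the seed
ensemble: the per-seed energies are recorded and adjudication is left to
the user rather than hidden behind a heuristic.

## Numerical choices and problem sizes

The test suite runs everything at desk scale, chosen to keep the suite
in minutes while leaving the physics measurable: thermostat checks on a
3,000-bead water box over 5,000 steps (time-averaged kinetic temperature
within 2% of `kBT`); shear measurements on 10 `rc` water boxes over a
few thousand steps; membrane checks on a preassembled 12 x 12 x 14 `rc`
bilayer whose leaflet coverage matches the production areal density
(1.5 `rc^2` per lipid) over 10,000 steps. At that scale the bilayer
persists under weak shear, the single-tail species' head order exceeds
the double-tail species', the tension extrema localize at the
lipid–water interfaces, and the steady shape factors land near the
production values (~0.9 rod-like for type 1, ~0.5–0.6 for type 2). One
production-scale claim does *not* carry down: the in-plane-vs-normal
gyration ordering of membrane chains, which at desk scale stays
normal-dominated (or flow-tilted under strong shear, breaking x–y
symmetry). The corresponding assertion is kept at its production form in
the scientific checks rather than weakened; the full-scale drivers in
`inst/scripts/long_runs.R` reproduce the production geometry
(30 `rc` box, 600 + 600 lipids, 200,000 steps, `W` = 6 and 1) where the
reported steady-state values (shear rates ~0.073 / ~0.168, order values
~0.74 / ~0.40) live.

## Known limitations

No electrostatics, no rigid constraints, no chemistry-specific bead
mappings; shear is momentum-swap only (no Lees–Edwards or SLLOD); the
classifier's vesicle label does not separate micelles from true
water-enclosing vesicles at small sizes; and single-frame pressure
profiles are noisy — steady-state windows (the last quarter of a run by
default in `cli_analyze()`) should be averaged.
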