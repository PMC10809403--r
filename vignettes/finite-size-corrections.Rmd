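---
title: "Finite-size electrostatic corrections and periodic-box diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finite-size electrostatic corrections and periodic-box diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finsize)
```

## The problem

Molecular simulations treat long-range Coulomb interactions with lattice-sum
(Ewald-type) methods in a periodic box of finite edge length $L$. A charged or
strongly dipolar solute then interacts with its own periodic images and, if
the box carries a net charge, with an implicit uniform neutralizing
background. Both effects bias computed free energies and even the sampled
conformational ensemble. The artifacts are most severe in alchemical
free-energy calculations that change a solute's net charge: the leading error
is the Wigner self-interaction of the changed charge,
$\Delta E \approx -\xi_{EW} f q^2 / (2L)$ with $\xi_{EW} \approx 2.837297$ and
$f = 138.935458$ kJ mol$^{-1}$ nm e$^{-2}$, which decays only as $1/L$.

`finsize` implements, at desk scale and on fully synthetic inputs, the three
ingredients needed to quantify and avoid these artifacts:

1. **A posteriori corrections.** $\Delta G_{pol}$ (solvent polarization:
   periodic vs. nonperiodic continuum solvation from a finite-difference
   Poisson solver) and $\Delta G_{dir}$ (direct interactions: lattice-sum
   vs. exact Coulomb energy of the perturbed group). The corrected free
   energy is $\Delta G_{raw} + \Delta G_{pol} + \Delta G_{dir}$, a sign
   convention chosen so both terms vanish for artifact-free setups. The
   third classical term, $\Delta G_{dsm}$ (discrete-solvent summation and
   interface potential), is exactly zero for charge-conserving perturbations
   in neutral boxes and is carried as a documented zero
   (`delta_g_dsm()`).
2. **Avoidance by construction.** A coalchemical-ion bookkeeping builder
   (`build_coalchemical_perturbation()`) that compensates any solute charge
   change with an opposite change on a restrained ion, and in its
   `neutral-box` mode additionally zeroes the total box charge at state A —
   hence, under linear charge interpolation, at all 11 default $\lambda$
   windows (`validate_neutrality()`).
3. **Diagnostics.** Minimal distance to the box wall (half the minimal
   periodic self-image distance), end-to-end free-energy profiles and basin
   populations with replica confidence intervals, orientation maps on the
   sphere, and box-size series referenced to the largest box.

## Energetic machinery

### Lattice-sum module

`ewald_energy()` is a plain (non-mesh) Ewald sum: erfc-screened real-space
part over minimum images within `r_cut` (default 1.0 nm, never more than
$L/2$), an exact reciprocal-space sum, the Gaussian self term, and the
background term $-\pi f q_{tot}^2/(2\alpha^2 V)$ so that legacy
constant-charge (non-neutral) topologies are computable. The splitting
parameter defaults to $\alpha = 3/r_{cut}$ and the reciprocal cutoff is
chosen from `rel_tol` (default $10^{-5}$). Exactness at small system size was
preferred over mesh interpolation speed: the plain sum doubles as the
reference for any future mesh implementation. The default boundary condition
is tinfoil (conducting), the common molecular-dynamics convention; a vacuum
boundary adds the surface-dipole term $2\pi f |M|^2/(3V)$.

`brute_force_lattice_energy()` is the independent oracle: a direct sum over
complete image cells in cubic shells with Evjen half-weights on the boundary
shell. Two properties of this construction matter and are documented because
they are easy to get wrong:

* Summing *complete neutral cells* over cubic shells converges to the
  **vacuum-boundary** value (the surface-dipole term is implicitly included).
  In the default tinfoil convention the oracle therefore subtracts the
  closed-form cell-dipole term, keeping it directly comparable with
  `ewald_energy()`.
* For a low-symmetry cell the truncation error decays as $1/S^2$ in the
  shell count $S$ (the truncated quadrupole-lattice tail). By default the
  oracle Richardson-extrapolates the sums at $S$ and $S-2$ in that known
  power; `extrapolate = FALSE` gives the raw sum for convergence studies.

On the 8-atom rock-salt cell the oracle reproduces the Madelung constant
(1.747565) to $10^{-6}$ at $S = 8$, and it agrees with the Ewald sum to
better than $10^{-5}$ relative on random neutral charge clouds.

### Poisson module

`solve_poisson_fd()` relaxes the 7-point finite-difference discretization of
$\nabla\!\cdot\!(\varepsilon\nabla\phi) - \varepsilon_{out}\kappa^2\phi\,s =
-4\pi f\rho$ (red-black successive over-relaxation, C++ kernel) under either
periodic or Coulomb-Dirichlet boundaries, to a relative residual of
$10^{-6}$ by default. `solve_poisson_fft()` inverts exactly the same
discrete operator spectrally for uniform permittivity; the two agree to the
solver tolerance, which is tested.

Numerical choices:

* **Cavity model.** Sharp dielectric boundary: $\varepsilon_{in}$ (default 1)
  inside any atom sphere, $\varepsilon_{out}$ outside. Each grid edge takes
  the harmonic average of the permittivity along it, weighted by the exact
  fraction of the edge inside the cavity union — the flux-conserving
  discretization for an interface crossing an edge. A plain two-cell
  harmonic mean would bias the effective cavity radius by about half a grid
  spacing (with $\varepsilon_{out} \approx 66$ the harmonic mean of a
  crossing edge collapses to $\approx 2\varepsilon_{in}$); the
  fraction-weighted form removes that bias, and the Born test below
  quantifies what remains.
* **Self-energy removal.** The solvation free energy is
  $\tfrac12\sum_i q_i[\phi_{het}(r_i) - \phi_{vac}(r_i)]$ where the vacuum
  solve repeats the *identical grid computation* with
  $\varepsilon \equiv \varepsilon_{in}$. The grid self-energy of the spread
  charges cancels exactly by construction instead of relying on an analytic
  subtraction with a different discretization error.
* **Nonperiodic reference.** A padded grid (default 3 times the solute
  extent, configurable) with Dirichlet values from the
  $\varepsilon$-screened Coulomb potential of the charges; cavities must
  stay at least one cell inside the boundary.
* **Periodic net charge.** The mean source is subtracted (uniform
  neutralizing background) and the potential is gauge-fixed to zero mean,
  mirroring the lattice-sum convention.
* **Charge assignment.** Trilinear (cloud-in-cell) spreading and the same
  trilinear interpolation for readout; the grid charge equals the net charge
  to machine precision.
* **Resolution.** The cavity radius should span at least two grid cells:
  below that the periodic-image (Wigner) content of the solve degrades
  noticeably. The default spacing is 0.05 nm. For the single-ion Born
  fixture ($q = 1\,e$, $R = 0.2$ nm, $\varepsilon_{out} = 66.6$) the
  nonperiodic solve is within 3% of the analytic Born value at the default
  spacing and converges monotonically under refinement — this is the
  module's calibration test, since the grid parameters of the original
  correction program are not public and no agreement with it is claimed.

### Solvent permittivity

The default $\varepsilon_{out} = 66.6$ is the value of the SPC-like
three-point water model the workflow targets; 78 may be chosen instead
(`grid_spec(eps_out = 78)`, `fs_constants(eps_solvent = 78)`). The choice
shifts $\Delta G_{pol}$ by a box-size-independent offset, so it never changes
box-size trends but does change absolute corrections — every report therefore
echoes it. The optional `kappa` parameter adds a linearized screening term in
the solvent region only; anything beyond that (nonlinear
Poisson-Boltzmann, explicit salt corrections) is out of scope.

### Correction averaging

`delta_g_pol()` and `delta_g_dir()` average per-snapshot differences over the
end-state configurations (the workflow they model uses 20 snapshots per end
state) and report the standard error over snapshots. Whether one averages the
per-snapshot $\Delta\Delta G$ before or after the B$-$A subtraction is
immaterial for the mean (linearity); the per-snapshot breakdown is kept in
the result so either view can be reconstructed. The perturbed group is all
atoms tagged `host`, `solute`, or `coion`; all pairs within the group are
included in $\Delta G_{dir}$ (whether the original implementation excluded
bonded pairs is not documented; including all pairs is the convention here
and cancels in any end-state difference where the geometry is fixed).

## The coalchemical builder

`build_coalchemical_perturbation(host_charge, c(q_A, q_B), ion_start, mode)`
always enforces charge conservation,
$q_{ion}^B = q_{ion}^A - (q_{solute}^B - q_{solute}^A)$. In `neutral-box`
mode the environment must additionally neutralize state A; any required
static counter-ion complement is *reported* (`counter_ions_to_add`), never
silently inserted, and a fractional residual raises an error. The
`constant-charge` mode reproduces the legacy setups in which the box may
carry a constant net charge that the lattice-sum background absorbs — the
case the corrections exist for. Ion species are metadata; the energetics
modules see only charges. The accompanying restraint
(`make_restraint()`) is harmonic with $r_0 = 2.25$ nm and
$k = 1000$ kJ mol$^{-1}$ nm$^{-2}$, the published setup values; the harmonic
form is an assumption (only $r_0$ and $k$ are published).

## Ensemble diagnostics

* `min_image_self_distance()` halves the minimal distance between any atom
  and any atom of the 26 neighbour images; for a point particle this is
  exactly $L/2$ and it is translation invariant.
* `wall_distance_summary()` reports `init` (first structure), `avg`, and
  `min`. The published table this mirrors is ambiguous about whether `avg`
  averages per-frame values or per-replica minima; the default is the mean
  over all frames, with `avg_mode = "replica_min"` as the alternative.
* `free_energy_profile()` Boltzmann-inverts per-replica histograms
  ($-k_BT\log p$, empty bins absent rather than zero), anchors the replica
  mean at zero, and reports $1.96\,SE$ confidence bands over replicas —
  the normal-approximation convention of the source workflow (50 replicas
  there; with few replicas these bands undercover and a t-quantile would be
  wider).
* `basin_delta_g()` counts conformers in two disjoint distance windows.
  The default windows, A $= [0.4, 0.9)$ nm (salt-bridge contact) and
  B $= [1.8, 2.6)$ nm (extended), are implementation defaults — the
  published figure regions are not numeric — and should be set explicitly
  for real data. Note the estimator measures the population *inside the
  windows*: for a Gaussian basin of width $\sigma$ a window edge at
  $2.5\sigma$ from the basin centre already shifts the ratio by about 1%.
* `orientation_map()` bins unit vectors on an equal-area partition
  (uniform in $\cos\theta$ times uniform in $\phi$), so isotropy is exactly
  uniform occupancy and a plain $\chi^2$ test applies. The face-alignment
  score is the fraction of vectors within angular radius $\rho$ (default
  20°) of the six cube-face directions, with isotropic expectation
  $3(1-\cos\rho)$ — the fingerprint of periodic-image orientational
  trapping of elongated solutes.
* `box_series()` compares each box against the largest simulated box with
  $1.96\sqrt{SE_{box}^2 + SE_{largest}^2}$ intervals; by construction the
  largest box's difference is zero, so "significant" means "distinguishable
  from the converged-box limit".
* Equilibration discard is a fraction (default 0.1 in
  `discard_equilibration()`), mirroring discarding the first tenth of each
  trajectory. Temperature defaults to 300 K everywhere.

## What the synthetic generators emulate — and what they do not

The fixtures module generates every test input: a Born ion (analytic
solvation oracle), rock-salt cells (Madelung oracle), random neutral charge
clouds (lattice-sum oracle inputs), an ideal helical alanine octapeptide,
Gaussian two-state distance samplers, and isotropic / six-face von
Mises-Fisher orientation ensembles. All are deterministic under a fixed
seed and restore the caller's RNG state.

The helix is built by torsion-driven chain extension with textbook peptide
geometry ($\phi = -57°$, $\psi = -47°$, $\omega = 180°$, standard bond
lengths and angles), a protonated N-terminus (three amine hydrogens), a
deprotonated carboxylate C-terminus, polar amide hydrogens and united-atom
side chains (one CB pseudo-atom, no aliphatic hydrogens), aligned with its
CA1-to-CA8 axis along $z$ and centred in the box. Its end-to-end distance is
1.29 nm and its axial span including the terminal hydrogens and carboxylate
oxygens is 1.46 nm; force-field-minimized starting structures of the same
peptide are slightly more compact (published initial wall distances imply
roughly 1.2-1.3 nm), so wall-distance fixtures agree with the published
starting values at the 0.1 nm precision of that table but can sit at the
edge of it.

Passing tests on these fixtures shows the estimators and solvers are
correct, not that any real simulation is converged: the two-state sampler
has no autocorrelation (real trajectories require the equilibration discard
and give wider intervals), the orientation mixture is an idealization of
image-induced trapping, and the charge clouds have no excluded-volume
structure beyond a minimum separation.

## Problem sizes and scale

The package is exercised at desk scale: grids of $32^3$-$96^3$ points,
systems of 1-64 charges, $10^3$-$10^4$ ensemble samples per replica. The
box-scaling study in the test suite uses the Born charging fixture
($q: 0 \to 1\,e$, $R = 0.4$ nm so the cavity spans at least two cells in
every box) over $L \in \{3, 4.5, 6, 9\}$ nm on $48^3$ grids, where the
polarization correction follows the expected $1/L$ Wigner scaling within a
few percent and dipolar (net-zero) perturbations show artifacts more than
five times smaller than monopolar ones — the quantitative core of the
"keep the box neutral" recommendation. Production-scale reproduction of
microsecond trajectory ensembles is explicitly out of scope.

## Known limitations

* Cubic boxes only; non-cubic input is rejected rather than truncated.
* Plain Ewald and plain SOR: appropriate for fixture-scale systems, not for
  thousands of atoms or $256^3$ grids (no mesh interpolation, no multigrid).
* Cavity radii are user input (via the charge table); no force-field radii
  are bundled.
* The linearized `kappa` screening term is the only salt effect in the
  Poisson module; the Galvani / interface-potential contribution is not
  computed (zero for the supported charge-conserving neutral-box setups).
* `delta_g_dir` includes all intra-group pairs (no bonded exclusions).
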