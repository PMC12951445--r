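---
title: "Electrostatic tuning analysis of flavin photoreceptor domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrostatic tuning analysis of flavin photoreceptor domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavotune)
library(dplyr)
```

## The scientific problem

LOV (Light–Oxygen–Voltage) photoreceptor domains bind a flavin chromophore
whose photochemistry starts with absorption into the bright singlet
π,π\* state, followed by intersystem crossing into a triplet n,π\* state
localised on the N5 lone pair. The rate and yield of that crossing depend on
the singlet–triplet energy gap, and the gap in turn is tuned by the
electrostatic environment the protein projects onto the isoalloxazine ring
system. LOV1- and LOV2-type domains differ systematically in that
environment: a more positive potential near the N5/C4 face stabilises the
singlet and destabilises the triplet (widening the gap and red-shifting
absorption), a more negative, diffuse potential does the opposite.

`flavotune` implements the classical-electrostatics side of this analysis as
a reusable, tested pipeline:

1. **Spectral tuning maps (ESTMs)** — the excitation-energy shift a probe
   charge induces from each point of a surface two van der Waals radii from
   the chromophore's heavy atoms.
2. **Electrostatic projection maps (EPMs)** — the protein's potential
   sampled onto the surface one van der Waals radius out, by averaging the
   nearest grid nodes of a potential map.
3. **Averaged-configuration environments (ASEC)** — many trajectory
   snapshots merged into one point-charge cloud with charges scaled by 1/N.
4. **Flexibility analysis** — per-residue Cα RMSF, normalisation,
   above-average selection, and chromophore-proximity counting.
5. **Linear interpolation paths (LIIC)** — equally spaced Cartesian
   geometries between two conformers, extended by extrapolation.

The quantum-chemistry and molecular-dynamics engines that produce the
inputs of the original analysis are outside the package's scope; a seeded
synthetic-data module generates physically structured stand-ins so every
stage runs and is testable at desk scale.

## The first-order tuning model

The package's central approximation is first order in the environment. Let
$\Delta q_i$ be the difference between excited- and ground-state partial
charges on chromophore atom $i$ (a zero-sum vector, since excitation
conserves charge). A probe charge $q_p$ at surface point $p$ shifts the
vertical excitation energy by

$$\Delta E(p) = k_C \, q_p \sum_i \frac{\Delta q_i}{|p - r_i|},$$

with $k_C$ the Coulomb constant. An extended environment with potential
$\phi_i$ at atom $i$ (in kT/e) shifts the state by
$\Delta E = k T \sum_i \phi_i\, \Delta q_i$, and the singlet–triplet gap by
$\Delta_{gap} = \Delta E_{T} - \Delta E_{S}$ (positive = widening). These
are the same bilinear form evaluated two ways, and the package keeps them
algebraically consistent: the eV-scale Coulomb constant is *derived* as
332.0636 / 23.0605 eV·Å/e², so a tuning-map value at point $p$ equals the
environment-shift of a point charge at $p$ to machine precision (this
equality is a property test).

**Sign convention** (the most error-prone contract): positive shift =
blue-shift = destabilisation of the excited state relative to the ground
state; negative = red-shift. A positive probe in a region of negative
difference charge red-shifts the state.

What first order leaves out: polarisation and induction of the chromophore
density by the probe, charge transfer, and vibronic (Franck–Condon)
effects. Maps computed with the packaged synthetic kernels are therefore
qualitative — right sign structure and magnitude scale, not per-point
values from any electronic-structure calculation. Users with computed
difference charges can supply them via `read_delta_charges()` and obtain
quantitatively meaningful first-order maps.

## Surfaces

Probe positions are laid on a deterministic golden-angle (Fibonacci)
lattice per heavy atom, at `scale` times the atom's van der Waals radius,
with per-atom counts proportional to the sphere area and a default density
of 1 point/Å². Candidates strictly inside any *other* heavy atom's scaled
sphere are pruned (tolerance 1e−9 Å; exact ties are kept — a measure-zero
case retained for stability). Hydrogens neither seed nor prune; the
analysis is a heavy-atom one throughout. The deterministic lattice makes
clouds byte-identical across runs, so tests can be exact; map *values* are
insensitive to density, but point *counts* scale with it.

Tuning maps default to `scale = 2`, projection maps to `scale = 1`; both
are overridable for radius-sweep studies.

## Potential fields and grids

The package evaluates uniform-dielectric, optionally Debye-screened Coulomb
potentials of point-charge sets,

$$\phi(p) = \frac{k_C}{\varepsilon\, k T}\sum_i q_i \frac{e^{-\kappa d_i}}{d_i} \quad [kT/e],$$

by a brute-force double loop — desk-scale charge counts make O(n·m)
acceptable and exactly testable. This is a stand-in for an external
Poisson–Boltzmann solver, whose run parameters the analysis protocol does
not pin down; crucially, the *projection machinery is identical either
way*, and solver-written OpenDX grids are read directly with `read_dx()`.

Grids are node-centred with both boundary planes included: a 64 Å cube at
0.5 Å spacing gives 129 nodes per axis, 2,146,689 in total — the unique
convention consistent with that printed node count. The default
temperature for the kT scale is 298.15 K. Energy bridges are fixed at
1 eV = 23.0605 kcal/mol and kT(T) = RT with R = 1.98720e−3 kcal/(mol·K);
round trips are exact to 1e−12.

## Projection rule

The projected value at a surface point is the *unweighted mean of the 8
nearest grid nodes* by Euclidean distance. This is deliberately not
trilinear interpolation: near a node the two rules differ, and the stated
protocol is the nearest-8 average. Trilinear interpolation is available as
`method = "trilinear"` for comparison. Off-lattice, "nearest 8" could also
be read as "the enclosing cell's corners"; the true-nearest reading is
implemented (they coincide for points well inside a cell).

Neighbour search uses an index-window search on the regular grid that
provably returns the same set as exhaustive search (the window grows until
every excluded node is farther than the m-th candidate); equality with
exhaustive search is property-tested on random configurations. Distance
ties are broken by lexicographic node index for reproducibility. Accuracy
against the analytic Coulomb potential of a single charge is about 0.6% at
0.25 Å spacing and improves monotonically with refinement (first order in
spacing, as expected for an uncentred average of a smooth field).

Display clipping defaults to ±0.25 kT/e, the conventional colour scale for
these projections; values outside the range are clipped only in the
`clipped_value` export column, never in the analysis.

## ASEC construction

"Merging with charges scaled accordingly" is interpreted as $q_i/N$ per
snapshot copy, which makes the merged cloud's potential equal the mean of
per-frame potentials at every external point (a tested identity), and —
optionally — Lennard-Jones $\varepsilon_i/N$ with $\sigma_i$ unchanged,
which reproduces the frame-averaged dispersion sum. The LJ scaling is an
interpretation, not a protocol fact; both scaled and unscaled modes exist.

Boundary treatment near a QM/MM link atom zeroes the designated MM charges
and splits their total equally among the recipient set; total charge is
conserved to 1e−12. Convergence of the iterative protocol is declared when
the last 4 excitation energies span at most 0.02 eV (max − min over the
window — the literal reading of "within ... of one another", rather than a
successive-difference rule). Which state's energy drives convergence is
the caller's choice; the loop driver takes a pluggable energy callback
because the quantum-chemistry step is external by design.

## Flexibility analysis

RMSF is computed per residue from the Cα after least-squares (Kabsch)
superposition onto an iterated mean structure (two refinement passes —
standard convention, as the protocol leaves alignment unstated).
Normalisation is the affine map to [0, 1]; constant profiles map to zero
with a degeneracy flag. "Above average" selection is strict inequality on
normalised values. Proximity uses an *inclusive* ≤ 4.0 Å cutoff between
heavy atoms (protocols mix "<4 Å" and "within 4 Å"; the difference touches
only exact-boundary atoms and the choice is documented here).

A statistical point that matters for validation: rigid-body superposition
absorbs 6 degrees of freedom of the fluctuation field, and the absorbed
rotational share grows with an atom's lever arm about the centroid. For an
extended chain the end residues can lose ~10% of their apparent RMSF; for
a compact, domain-like arrangement of n residues the absorbed share is
only ~2/n of the variance. The synthetic trajectory generator therefore
lays its Cα sites on a compact globular shell (3.8 Å neighbour spacing),
and the recovery tests use a domain-sized residue count (100, about the
size of a LOV core). Under those conditions a prescribed per-axis σ is
recovered as σ√3 within 5% at 12,000 frames (the package's tested claim).
What the synthetic trajectories do *not* emulate: anharmonic and
correlated motions, slow conformational transitions, and solvent drag —
so passing recovery tests validate the RMSF estimator, not any force
field.

## Interpolation paths

`build_path()` linearly interpolates Cartesian coordinates between two
geometries and extrapolates the same step beyond both ends. The protocol
fixes only the total of 21 geometries; the 15 + 2×3 split is this
package's default and is configurable and recorded in the output manifest.
Endpoints are returned bit-identical to the inputs and equal spacing holds
to 1e−9 Å. No re-superposition of the second endpoint is done by default —
geometries from one protein frame already share an axis system — but
`prealign = TRUE` Kabsch-aligns free molecules first.

## Synthetic-data design

* **Toy flavin**: 17 heavy atoms, three linearly fused idealised hexagons
  (1.4 Å bonds) in the isoalloxazine layout, with the field's site labels
  (N1, C2, N3, C4, C4a, N5, N10, O2, O4) and a one-label-per-atom ring
  partition (bridgeheads assigned to the central ring).
* **Difference-charge kernels**: zero-sum by construction. The singlet
  kernel is negative on N5/C4 and the lower central/pyrimidine edge and
  positive on the xylene side; the triplet kernel is positive on N5
  (+0.10 e) and weakly on C4. Magnitudes were chosen once so that map
  extrema at a +0.1 e probe on the 2× surface land at order 0.01–0.05 eV —
  a scale match to the reported maps, never a value match.
* **Environments**: `LOV1_like` is a +0.5 e point 3 Å below the N5/C4
  face; `LOV2_like` is the mirrored −0.5 e point plus a diffuse −0.05 e
  shell under the xylene ring. These are minimal motifs that force the
  documented sign structure (LOV1-like: singlet red-shift and gap
  widening; LOV2-like: gap narrowing), which the pipeline then *measures*
  rather than assumes.
* **Trajectories**: independent per-frame Gaussian displacements with
  prescribed per-residue σ on the compact shell described above; optional
  global rigid jitter (off by default, isolating fluctuation recovery from
  superposition quality). Seeded via an RNG-state-preserving local seed.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the full-geometry grid
check (129³ nodes, empty charge set), projection-oracle grids up to 33³
nodes with charges, surface clouds of a few hundred points, and a
12,000-frame × 100-residue recovery trajectory; the complete suite runs in
well under a minute. Degenerate inputs are handled explicitly: empty
charge sets give zero potential, constant RMSF profiles normalise to zero
with a flag, all-zero map pairs give zero capacity flagged degenerate, and
identical path endpoints give a constant path.

## Known limitations

* First-order electrostatics only; packaged kernels are qualitative
  stand-ins and carry no electronic-structure provenance.
* The screened-Coulomb field is not a Poisson–Boltzmann solution (no
  dielectric boundary, no ionic accessibility); quantitative projection
  maps should come from a solver-written DX grid.
* PQR parsing is whitespace-delimited (the converter convention), not
  fixed-width; unusual fixed-width PQR dialects are not supported.
* The Amber/Bondi-style radius table is a single bundled set; the exact
  radius variant used by any given structure-preparation chain should be
  supplied via the override when it matters.
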