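# flavotune

Electrostatic tuning analysis for flavin-binding photoreceptor (LOV)
domains, in R.

## The problem

LOV domains start their photocycle by exciting a flavin chromophore into
the bright singlet π,π\* state, which crosses over to a triplet n,π\* state
localised on the flavin's N5 lone pair. How fast and how completely that
intersystem crossing happens depends on the singlet–triplet energy gap —
and the gap is tuned by the electrostatic field the protein projects onto
the isoalloxazine ring system. A positive potential near the N5/C4 face
stabilises the singlet and destabilises the triplet (widening the gap and
red-shifting absorption, the LOV1-type signature); a diffuse negative
potential narrows the gap (the LOV2-type signature).

`flavotune` is for computational (photo)biophysicists who want to quantify
that tuning without re-running heavy quantum chemistry. Its core is a
first-order model built on per-atom *difference charges*
Δq<sub>i</sub> (excited minus ground state, zero-sum):

- **Spectral tuning map (ESTM)** — shift induced by a probe charge
  q<sub>p</sub> at surface point p, two van der Waals radii from the
  chromophore:
  ΔE(p) = k<sub>C</sub> q<sub>p</sub> Σ<sub>i</sub> Δq<sub>i</sub> / |p − r<sub>i</sub>|
  (eV; positive = blue-shift).
- **Electrostatic projection map (EPM)** — the protein's potential grid
  (computed in-package by screened Coulomb sums, or read from a
  Poisson–Boltzmann solver's OpenDX file) averaged over the 8 nearest grid
  nodes at each point of the 1× van der Waals surface (kT/e).
- **Environment shift / gap shift** —
  ΔE = kT Σ<sub>i</sub> φ<sub>i</sub> Δq<sub>i</sub> per state, and
  Δ<sub>gap</sub> = ΔE<sub>Tn</sub> − ΔE<sub>S1</sub> (positive = gap
  widening).

Around the core sit the supporting stages of the full analysis: PDB / PQR /
OpenDX / XYZ input-output, deterministic van der Waals surface sampling,
averaged-configuration (ASEC) point-charge environments from trajectory
snapshots (charges scaled 1/N), per-residue Cα RMSF flexibility analysis
with B-factor export, chromophore-proximity residue selection, and
21-geometry linear-interpolation (LIIC) reaction paths. A seeded
synthetic-data module (toy flavin, qualitative difference-charge kernels,
LOV1-like / LOV2-like charge motifs, Gaussian trajectories) makes every
stage runnable and testable without external engines.

## Worked example

```r
library(flavotune)

mol    <- make_toy_flavin()
cloud  <- assign_point_regions(generate_surface(mol, scale = 2, density = 1), mol)
map_s1 <- estm_map(mol, make_delta_charges("S1_pipi", mol), probe = 0.1, cloud = cloud)
map_tn <- estm_map(mol, make_delta_charges("Tn_npi", mol), probe = 0.1, cloud = cloud)
glance(map_s1)
#> # A tibble: 1 × 5
#>   state   probe n_points max_redshift max_blueshift
#>   <chr>   <dbl>    <int>        <dbl>         <dbl>
#> 1 S1_pipi   0.1      412      -0.0282        0.0304

gap_report(map_s1, map_tn)
#> <gap_report>
#>   max S1 red-shift:  -0.02817 eV
#>   max Tn blue-shift: 0.02488 eV
#>   combined capacity: 0.05305 eV
```

A +0.1 e probe moved over the 2× van der Waals surface (412 points) can
red-shift the synthetic singlet by at most 28 meV and blue-shift the
synthetic triplet by at most 25 meV; placed optimally, a single charge
could therefore widen the singlet–triplet gap by up to 53 meV (the
packaged kernels are qualitative stand-ins, so these are scale-level
numbers, not predictions for lumiflavin).

A LOV1-like environment (+0.5 e under the N5/C4 face) seen through the
same kernels:

```r
env <- make_environment("LOV1_like", mol)
phi <- potential_at_atoms(mol, env)
gap_shift(mol, make_delta_charges("S1_pipi", mol),
          make_delta_charges("Tn_npi", mol), phi)
#> [1] 0.2305696   # eV > 0: the gap widens, as expected for LOV1
```

And the projection route — evaluate the environment's potential on a grid,
project it onto the chromophore surface and summarise by ring region:

```r
grid <- evaluate_grid(env, box_edge = 16, spacing = 0.5,
                      center = colMeans(as.matrix(heavy_atoms(mol)[, c("x","y","z")])))
epm  <- project(grid, assign_point_regions(generate_surface(mol, 1, 1), mol))
summarize_regions(epm)
#> # A tibble: 6 × 6
#>   region       mean   min   max n_points sign
#>   <chr>       <dbl> <dbl> <dbl>    <int> <chr>
#> 1 central      87.4  47.9 201.        43 positive
#> 2 pyrimidine   67.8  47.5 176.        35 positive
#> 3 substituent  58.4  40.1 136.        62 positive
#> 4 xylene       48.9  36.3  87.8       63 positive
#> 5 N5/C4        87.8  56.3 176.        19 positive
#> 6 C2/N3        65.1  47.5  96.9       19 positive
```

The N5/C4 face carries the strongest positive mean potential, which is
exactly the face whose polarity separates LOV1-type from LOV2-type
electrostatics. `autoplot()` renders any map; `export_colored()` writes
CSV plus a pseudo-atom PDB (value in the B-factor column, clipped to
±0.25 kT/e) for molecular-graphics programs; `run_pipeline()` chains
every stage and writes a JSON report.

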