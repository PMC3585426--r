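---
title: "Collective helix motions in four-helix bundles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collective helix motions in four-helix bundles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixcv)
```

## The problem

HAMP-like signal-relay domains are dimeric, parallel four-helix bundles
(helices N1, C1 of monomer 1 and N2, C2 of monomer 2) whose conformational
states are thought to differ by small rigid-body motions of the helices:
an axial *piston* shift of 1-2 Angstrom, an axial *rotation* of tens of
degrees (the "gearbox" picture), and changes in the *tilt* angle between
helices or monomers. `helixcv` provides these three motions as collective
variables (CVs) with analytic gradients suitable for biased sampling,
trajectory-level bundle analyses, a well-tempered metadynamics engine with
reweighting that runs on toy Langevin systems, and a synthetic bundle
generator that creates structures with exactly known CV coordinates.

## The collective variables

Each helix is represented by a vector `V = H - T`, where `H` and `T` are
the unweighted centers of mass of four consecutive C-alpha atoms at the
helix head and tail (one full helical turn each), and by the midpoint
`M = (H + T)/2`. For piston and rotation a reference structure is first
superposed onto the current frame (Kabsch, no reflection, unweighted) over
the helical C-alpha selection, removing overall translation and rotation.

* **Piston** (Angstrom): `Z = (M - M0') . V/|V|`, the displacement of the
  helix midpoint from its aligned reference position `M0'`, projected onto
  the *current* axis direction. Positive values point toward the head
  group (the group listed first in the helix definition); the convention
  is recorded in the output metadata because only relative displacements
  are physically meaningful.
* **Rotation** (degrees, signed): the angle between the projections, onto
  the plane normal to `V`, of `r = R - M` and `r0 = R0' - M`, where `R` is
  the center of mass of the rotational-reference group (C-alpha atoms
  spaced four residues apart, well off the axis) and `R0'` its aligned
  reference counterpart. The angle is evaluated with `atan2`, which stays
  well-behaved as the magnitude approaches 180 degrees, and signed by the
  right-hand rule about `V/|V|` (counterclockwise looking from tail to
  head). Two anchorings of the reference azimuth vector are supported:
  against the current midpoint `M` (the default) or against the aligned
  reference midpoint `M0'`. The default couples `r0` weakly to the frame;
  the `"reference"` anchoring makes `r0` a constant, so the
  frozen-alignment gradient is exactly translation-invariant. The two
  differ only through the transverse component of `M - M0'`, which is
  small for intact bundles.
* **Tilt** (degrees): `arccos(V1 . V2 / |V1||V2|)` in [0, 180], between
  two helices or two monomers; for the monomer variant the head and tail
  groups pool the corresponding atoms of both helices of the monomer. No
  reference is needed and the value is invariant under any global rigid
  motion by construction.

### Gradients and the frozen-alignment approximation

The gradients of all three CVs with respect to the contributing atom
coordinates are analytic. For piston and rotation the aligned reference is
treated as a constant: the optimal rotation of the superposition is not
differentiated through. This is the standard practice for engine-ready CV
gradients and is validated by `numeric_gradient_check()`, which compares
the analytic gradient against central differences computed *with the
alignment frozen* (step within 1e-6 to 1e-3 Angstrom). On random
nondegenerate bundles the discrepancy is at the 1e-9 level, far below the
1e-4 working tolerance. An atom may belong to two defining groups (the
default rotational-reference residues overlap the head and tail
quadruples); its contributions add.

## Bundle analyses

* **Helical RMSD**: C-alpha RMSD after superposition over the helical
  selection. The default selection is residues 282-296 (N helices) and
  312-326 (C helices) of each chain; flexible termini and the inter-helix
  connector (297-311) are excluded so the measure reflects only the
  helices.
* **Helical hydrogen bonds**: a bond between residues i and i+4 is counted
  when the O(i)-N(i+4) distance is below 3.5 Angstrom and the
  acceptor-donor-hydrogen angle at the donor nitrogen is below 30 degrees.
  The angular threshold is configurable (30 degrees is the standard
  backbone criterion). When the structure carries no amide hydrogens, H is
  reconstructed at 1.01 Angstrom from N on the bisector of the N-CA and
  N-C(i+3) directions. Pairs with missing backbone atoms are skipped with
  a warning, never silently.
* **Crick-angle deviation**: per residue, the angle in the plane normal to
  the local helix axis between the direction from the helix axis toward
  the bundle axis and the direction to the residue's C-alpha, minus the
  ideal knobs-into-holes angle for its heptad position. The ideal ladder
  is configuration (`crick_ladder()`, default a = 19.5 degrees advancing
  720/7 degrees per residue) rather than hard-coded. The helix axis is fit
  through sliding-window C-alpha centroids (7 residues = two turns), which
  sit on the true axis to a small fraction of the helix radius; a raw
  per-atom principal-component fit tilts measurably with the azimuth-z
  correlation of a finite helix and was rejected for that reason.
* **Piston-state classification**: with threshold 0.5 Angstrom (midway
  between the resting-state fluctuation scale, about 0.16 Angstrom, and
  the 1-1.5 Angstrom shifted states), frames map to P00 (no shift), P10
  (N1 up, C2 down), P01 (N2 up, C1 down), P11 (both diagonal pairs), or
  OTHER. Any piston at or beyond 3 Angstrom marks an out-of-register
  candidate — a register shift of the hydrophobic layers corresponds to
  4-5 Angstrom and is treated as misfolding, so such frames are OTHER and
  flagged.
* **Surfaces**: `neg_log_probability_surface()` histograms 1D/2D CV
  samples (50 bins per axis over the observed range padded 5 percent, by
  default), returns `-ln p` in kT shifted to zero at the minimum, masks
  empty bins as NA (never zero-fills), and accepts per-frame weights from
  reweighting.

## Well-tempered metadynamics

Gaussian hills of initial height `h0` are deposited every `pace` ps; in
the well-tempered scheme the height decays with the instantaneous bias at
the deposition point, `h = h0 exp(-V(s, t) / (kB dT))`, with CV
temperature `dT = (gamma - 1) T` under the bias-factor convention
`gamma = (T + dT)/T`. The bias converges to `-dT/(T + dT) F`, so the free
energy is recovered as `F = -(T + dT)/dT V(s, t_end)`, shifted to zero at
its minimum. One-sided polynomial walls
`kappa ((s - s0)/r)^e` (defaults `e = 4`, `kappa = 500` kJ/mol, `r = 0.1`
in piston units and about 1 degree for angle CVs, all configurable)
confine the sampled range; they are exactly zero inside the bound and
C1-continuous at it. Angle CVs are treated as non-periodic because the
walls confine them well inside a period.

The toy engine integrates underdamped Langevin dynamics with the BAOAB
splitting (1 to 4 dimensions, built-in double-well and harmonic
potentials, reduced units: kJ/mol, ps, Angstrom-like lengths, mass in
kJ/mol ps^2 per length^2). The documented stability requirement
`dt * friction < 0.1` is enforced. A single integer seed drives one R RNG
stream used for both velocity initialization and the thermostat noise,
making runs bit-reproducible.

### Numerical choices

The deposited bias lives on a regular grid (default around 500 nodes per
axis): each hill is accumulated *exactly* — analytic value and derivative
at every node, no cutoff — and per-step forces interpolate the gradient
grid multilinearly. Because the replay in `free_energy_from_bias()` sums
the recorded hills in deposition order with the same node arithmetic, the
replayed bias is bit-identical to the in-run grid, and HILLS files are
written with 17 significant digits so the text round-trip preserves every
double. Excursions beyond the grid raise an error advising wider grids or
walls rather than silently extrapolating.

Wall stiffness interacts with the time step: the default piston wall
(`kappa = 500`, `r = 0.1`) has curvature of order 1e5 kJ/mol per unit^2
just outside the bound and needs `dt` of order 1e-3 ps at unit mass. The
double-well studies in the tests therefore use gentler confining walls
(`kappa = 100`, `r = 0.2` at +-1.8) with `dt = 0.002` ps and friction
5/ps.

### Reweighting

The time-dependent bias offset
`c(t) = (1/beta) ln[ int exp(beta gamma/(gamma-1) V) ds /
int exp(beta/(gamma-1) V) ds ]`
is updated once per hill on the free-energy grid, consistent with the
adiabatic-evolution assumption behind well-tempered reweighting. Frame
weights are `w_t ~ exp(beta [V(s_t, t) - c(t)])`, with `V(s_t, t)` the
exact hill sum over hills deposited up to `t`. A warning is raised when
the final bias at the grid boundary exceeds the interior minimum by more
than 1 kT (grid too narrow). In validation runs the first 20 percent of
frames are discarded as the filling transient before histogram
comparisons; agreement with a long unbiased reference is then within
statistical error (block standard errors over 25 contiguous blocks).

## The synthetic bundle generator

The generator is the package's source of ground truth. `build_ideal_helix()`
places C-alpha atoms exactly on the parametric helix (defaults: rise 1.5
Angstrom, twist 100 degrees, radius 2.3 Angstrom) and backbone N, C', O on
companion helices using fixed cylindrical offsets derived once from a
standard internal-coordinate build (phi = -57, psi = -47 degrees); at the
default geometry every i to i+4 hydrogen bond passes the 3.5 Angstrom /
30 degree criterion, so an n-residue helix has exactly n - 4 bonds.

`build_bundle()` arranges four helices (15 residues each by default, HAMP
numbering 282-296 / 312-326, rotational references 283/287/291/295 and
313/317/321/325) at azimuths 45, 135, 225, 315 degrees with their axes
tilted inward so they converge toward a tip on the C-terminal side. The
cone half-angle is solved from the requested inter-monomer tilt (default
18 degrees, the equilibrium value of the wild-type bundle; monomer tilt =
`2 atan(sqrt(2)/2 tan(alpha))`). Because the 4-atom end groups sit
slightly off the geometric axis, the realized tilt differs from the target
by a few tenths of a degree.

`inject_motion()` produces frames whose CV coordinates are *exact*:

* the monomer tilt is applied about the waist axis through the cone tip
  (perpendicular to the inter-monomer plane, tip held fixed);
* each helix is then rotated about its own axis — the line through its
  head and tail centers of mass, so the rotation moves neither `V` nor
  `M` — and translated along that axis;
* because the waist rotation genuinely displaces helix midpoints axially
  (piston and tilt are physically coupled — the same coupling the real
  bundle shows), small corrective axial translations and azimuthal
  rotations are applied per helix so the final piston and rotation CVs
  equal the requested values exactly, while leaving the tilt untouched.

Gaussian positional noise (i.i.d. per coordinate, given sd) is added last,
deterministically under a seed. What the generator does **not** emulate:
side chains, sequence, helix bending or fraying, solvent, and any
force-field energetics — synthetic tests therefore validate the
*measurement machinery* (CVs, gradients, analyses), not the conformational
thermodynamics of real HAMP domains, which enter only through externally
supplied trajectories.

For the Crick analysis the knobs-into-holes fixture uses heptad-periodic
geometry (twist 720/7 degrees per residue, 14 residues = two exact
heptads) with the azimuthal phase calibrated so the register residue faces
the bundle core at the ideal `a` angle; its deviations are then zero to
machine precision, and an injected 26 degree axial rotation shifts the
profile by 26 +- 3 degrees.

## Validation problem sizes

The shipped tests and the acceptance script use: noiseless recovery over
pistons of +-0.5 to 2 Angstrom, rotations +-10 to 30 degrees and tilt
increments 5 to 20 degrees; 20 random noisy fixtures for the gradient
check; double-well (barrier 5 kJ/mol) well-tempered runs of 2e4 ps
(dt = 0.002 ps, 1e4 hills, gamma = 10, h0 = 0.25 kJ/mol, sigma = 0.2,
pace 2 ps) over five seeds for barrier recovery, an 8e3 ps biased run
against a 2e3 ps unbiased reference for reweighting, and 1e6-step
equipartition checks. These sizes were chosen so each property is measured
well inside its tolerance (the barrier to about 0.1-0.2 kJ/mol, averages
to a few percent).

## Known limitations

* CV gradients freeze the superposition; biasing engines that require the
  exact derivative through the optimal rotation would need the additional
  alignment-response term.
* The rotation CV treats the helix as one rigid body; per-layer rotation
  (which real mutational intermediates show) is visible only through the
  per-residue Crick profile.
* Supported trajectory formats are multi-model PDB and DCD; compressed
  XTC is not read.
* The toy engine biases its own coordinates; coupling the CV gradients to
  a molecular-dynamics engine is out of scope.
* `-ln p` surfaces use fixed-width histograms; no kernel smoothing is
  applied, so sparsely sampled regions are masked rather than estimated.

## A worked example

```{r example, eval = FALSE}
b <- build_bundle()                       # reference bundle, tilt ~ 18 deg
p10 <- inject_motion(b$frame, b$bundle, b$ref,
                     piston = c(N1 = 1.0, C2 = -1.5))
al <- identity_alignment(b$ref)
z <- sapply(c("N1", "C1", "N2", "C2"), function(l)
  piston_cv(p10, b$ref, b$bundle$helices[[l]], aligned = al)$value)
z
#>   N1   C1   N2   C2
#>  1.0  0.0  0.0 -1.5
classify_piston_state(z)
#> [1] "P10"
```
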