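---
title: "Flexible-receptor docking in dockflex: models, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flexible-receptor docking in dockflex: models, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockflex)
```

dockflex is a headless engine for interactive-style receptor–ligand docking:
it evaluates nonbonded forces in real time rather than from a precomputed
force grid, gates rigid-body moves on collisions, deforms the receptor in
response to ligand forces by linear response, and reports hydrogen bonds and
the solvent-excluded surface per conformation. This vignette explains the
models, their assumptions, the tunable parameters, and the numerical and
design choices; the README shows the worked end-to-end example.

## Nonbonded model

The receptor–ligand interaction is a sum over atom pairs within a cutoff
(default 8 Å, strict `<`) of a 12-6 Lennard-Jones term in GROMOS C6/C12 form,

$$E_{LJ}(r) = \frac{C_{12}}{r^{12}} - \frac{C_6}{r^6},$$

and Coulomb's law screened by a distance-dependent relative permittivity
$\varepsilon_r(r) = D\,r$ with $D = 4\ \text{Å}^{-1}$ by default,

$$E_{el}(r) = \frac{k_e\,q_i q_j}{D\,r^2},$$

so the electrostatic force is $2 k_e q_i q_j / (D r^3)$, the exact derivative
of the implemented energy. The linear distance dependence is the most common
implicit-water screening choice in docking; a constant dielectric is
available. Units are Å, kJ/mol and elementary charges, with
$k_e = 1389.35458\ \text{kJ mol}^{-1}\,\text{Å}\,e^{-2}$ and
$k_b = 0.0083144621\ \text{kJ mol}^{-1}\text{K}^{-1}$.

Per-atom parameters are C6, C12, charge and a vdW radius, assigned from a
JSON table keyed by (residue, atom name). The bundled table covers only the
package's synthetic fixture chemistry; production work should supply a table
exported from a real force field. σ/ε entries are converted via
$C_6 = 4\varepsilon\sigma^6$, $C_{12} = 4\varepsilon\sigma^{12}$. Cross
terms combine geometrically on C6 and C12 (GROMOS style) by default;
Lorentz–Berthelot (arithmetic σ, geometric ε) is available for Amber-style
tables, with atoms lacking an LJ well contributing no LJ term.

Numerical choices: truncation at the cutoff is plain (no switching
function), so the energy is discontinuous there by the magnitude of one pair
term — energy–force consistency tests therefore keep probe displacements
away from the boundary. Pair distances are clamped at $10^{-6}$ Å so
degenerate synthetic inputs cannot overflow the kernel (clamped pairs are
counted in the report). Pair summation is in ascending index order, giving
bit-reproducible results on repeated evaluation.

The neighbor search is a cell list built over the rigid ligand's local
coordinates with cell size equal to the cutoff, so one query scans at most
27 cells; receptor atoms are mapped into the ligand frame by the inverse
ligand transform instead of rebuilding the grid per pose. Queries use the
same strict-`<` rule as the force kernel, so the grid path and a brute-force
double loop agree on the pair set exactly.

## Collision detection

Two schemes gate moves in a docking session:

* **Force mode** (default, mandatory with a flexible receptor): a move is a
  collision when the magnitude of the total force on the receptor exceeds a
  threshold. No canonical threshold exists in the literature; the default
  1000 kJ mol⁻¹ Å⁻¹ sits an order of magnitude above thermal-scale forces
  and below hard-clash forces for small ligands, is configurable, and is
  recorded in every session trace.
* **Overlap mode** (rigid docking): the maximum interatomic penetration
  $\max_{ij}(R_i + R_j - d_{ij})$ over in-cutoff pairs, floored at zero,
  compared against a tolerance (default 0 Å: any vdW overlap collides).
  It needs only vdW radii, so it works on structures without force-field
  parameters in the lenient element-fallback mode.

## Receptor flexibility by linear response

Receptor deformation under ligand forces is approximated from the
equilibrium fluctuations of the free receptor. Given the top-$M$ eigenpairs
$(\lambda_m, v_m)$ of the $3N \times 3N$ Cartesian covariance of atomic
fluctuations (e.g. from an MD ensemble), the displacement from the relaxed
coordinates $r_o$ under forces $f$ is

$$\Delta r = \beta\, V_M\, \mathrm{diag}(\lambda_M)\, V_M^{t}\, f,
\qquad \beta = 1/(k_b T),$$

evaluated as three matrix–vector products — the dense $3N \times 3N$
response matrix is never formed. Truncation to the leading "important
subspace" is what makes per-move relaxation cheap: most protein fluctuation
lives in a few collective modes, so small $M$ captures most of the response.

Because $f$ depends on the deformed coordinates, static equilibrium is a
fixed point, found by damped iteration
$\Delta r_{k+1} = (1-\alpha)\Delta r_k + \alpha\,\beta V\Lambda V^t f(r_o + \Delta r_k)$
from $\Delta r_0 = 0$. Defaults: $\alpha = 0.2$, tolerance $10^{-4}$ Å on
the max-norm change, 500 iterations. The damping stabilizes the
force–displacement feedback (steep LJ walls make the undamped map
overshoot); for constant forces the iteration is linear with contraction
factor $1-\alpha$ and converges monotonically. Non-convergence is flagged in
the result, never thrown, and the per-iteration trace is returned. The
procedure is deterministic: the same pose always relaxes to the same
deformation, the deliberate contrast with steering a live (stochastic) MD
simulation.

Model building from an $F \times 3N$ ensemble: frames are optionally (and by
default) Kabsch-superposed onto the first frame — otherwise rigid-body
motion dominates the spectrum — and the covariance uses the plain Cartesian
$1/F$ normalization with no mass weighting. For $F < 3N$ the eigenproblem is
solved through the $F \times F$ Gram matrix, avoiding the dense covariance
entirely. The relaxed structure $r_o$ is the ensemble frame with minimum
RMSD to the mean ("closest to average"; frame indices are 1-based, ties to
the lowest index), and the captured-fluctuation fraction
$\sum_{m \le M}\lambda_m / \mathrm{tr}(C)$ is reported so users can judge
their truncation. Degenerate eigenvalues leave individual eigenvectors
identified only up to rotation within their eigenspace; tests compare
subspace projectors, not raw vectors.

Frames: forces are computed in the world frame and rotated into the
receptor's model frame by the inverse receptor rotation before entering the
response formula; deformations are stored in the model frame and reset when
a response model is swapped, since $\Delta r$ is only meaningful in its own
model's subspace.

## Hydrogen bonds

A primary hydrogen bond is detected when the hydrogen–acceptor distance is
strictly below 2.5 Å and the donor–hydrogen–acceptor angle (measured at the
hydrogen, 180° = linear) is strictly above 90°, the McDonald–Thornton
geometric criteria. The angle convention matters: reading the "angle between
the D→H line and the H→A line" naively as a vector angle would make 0°
linear and invert the criterion; dockflex pins the 180°-linear convention in
tests. Donor and acceptor roles come from an editable JSON map (standard
amino acids, nucleotides, water, common sugars); hydrogens are associated to
the nearest heavy atom within 1.25 Å (covalent X–H bonds are 0.95–1.1 Å),
with CONECT records taking precedence. Structures without explicit
hydrogens cannot donate — detection then fails with an informative error
rather than silently returning nothing, since hydrogen placement is out of
scope. Acceptors are gridded and queried around each hydrogen with the same
cell-list machinery (and the same strict boundaries) as the force kernel.

## Solvent-excluded surface

The SES is triangulated per conformation from a signed scalar field sampled
on a regular grid (spacing 0.375 Å, or 0.75 Å for large structures — the
builder refuses grids above a node budget and advises coarsening):

1. the analytic signed distance to the solvent-accessible surface,
   $sd(x) = \min_i(|x - c_i| - (R_i + p))$ with probe radius $p$ (default
   1.4 Å, water), marks interior nodes ($sd < 0$);
2. a separable squared Euclidean distance transform gives each interior
   node its distance to the exterior node set;
3. the field is that distance minus $p$: positive inside the SES, negative
   outside, zero on the surface.

Because the node-set distance overestimates the true distance to the
exterior *region* by up to half a grid step, nodes near the zero level set
are refined: where the radial foot point on the nearest inflated sphere is
itself solvent-exposed (checked against all neighboring spheres), $-sd$ is
exactly the distance to the exterior and replaces the quantized estimate.
Convex (contact) patches — including the entire surface of an isolated atom
— thus interpolate at analytic accuracy, while re-entrant, probe-bridged
crevices keep the distance-transform estimate. An isolated atom's mesh area
converges to its vdW sphere area as the grid is refined.

Meshing is classic 256-case Marching Cubes with linear interpolation along
cube edges, vertices welded on shared edges, zero-area triangles dropped,
and orientation normalized so normals point toward decreasing field (out of
the molecule); vertex normals are area-weighted. Corner classification is
strictly "below iso = outside", which resolves nodes lying exactly on the
level set deterministically (at the cost of exact negation symmetry in that
measure-zero case). Meshes export as OBJ or PLY; the space-filling
depiction is exported as a JSON sphere list.

## Docking sessions

A session holds both molecules, their rigid transforms, the force field,
the collision configuration and an optional response model (which forces
force-mode collision). `propose_move()` applies a world-frame delta,
evaluates collision at the candidate pose, and either commits (relaxing the
receptor if flexible) or returns the prior state untouched — the headless
analogue of freezing the molecules on contact. Every event appends a trace
record (step, delta, acceptance, component energies, collision metric,
hydrogen-bond count); traces serialize as JSON-lines with 17 significant
digits so a replay reproduces the transform history bit-identically.
Component toggles re-relax a flexible receptor immediately, which is what
makes the salt-bridge scenario work: switching electrostatics off removes
the attraction holding a deformation, and the receptor falls back to
$r_o$. Ghost selections exclude atoms from forces, collisions and hydrogen
bonds while keeping them in the structure, surface and all output files.
`merge_complex()` emits the deformed, transformed complex as a single
molecule (chains re-lettered, serials renumbered) that can seed a new
session as its receptor.

## Synthetic data and what the tests do (and do not) show

All tests run on generated fixtures; no downloads are involved. The
generators are pure functions of their parameters and a seed (the global
RNG stream is saved and restored):

* `make_random_cloud(n, box, seed)` — uniform atoms with element-cycled
  parameters. The bundled element defaults carry zero charge, which would
  make electrostatic paths vacuous, so the generator cycles small
  mixed-sign charges (C +0.1, N −0.3, O −0.4, S +0.2, P +0.4 e).
* `make_docking_pair(...)` — a receptor cloud plus a ligand cloud
  rejection-sampled so no contact is closer than 1.7 Å. Uniform clouds
  occasionally interpenetrate vdW cores, where the $r^{-13}$ repulsion
  amplifies last-digit rounding into force differences far above any
  meaningful tolerance; real structures never do this, so the
  oracle-equivalence tests use the non-interpenetrating pair.
* `make_harmonic_ensemble(...)` — frames $base + \sum_m \sqrt{\lambda_m}
  z_m v_m + \text{noise}$ with orthonormalized planted directions, so the
  sample covariance converges to $\sum_m \lambda_m v_m v_m^t +
  \sigma^2 I$ and recovery of $(\lambda_m, v_m)$ has a known ground truth.
  Recovery tests use 5000 frames, where sampling error on the top
  eigenvalue is comfortably inside a 10% band.
* `make_hbond_geometry(d, angle)` — exact donor–hydrogen–acceptor
  placements for boundary tests; `make_hbond_cloud(...)` — random
  donor/acceptor fields for oracle equivalence.
* `make_salt_bridge_scene()` — a four-atom receptor (anionic site +
  cationic amine-like probe with two polar hydrogens) facing a one-atom
  anionic ligand, with a single response mode translating the probe
  between the two sites. Geometry, charges and the mode eigenvalue
  (λ = 0.2 Å², T = 300 K) were chosen once so the equilibrium deformation
  (≈0.64 Å toward the ligand) crosses both hydrogen-bond boundaries:
  electrostatics on breaks the internal bond and forms the ligand bond;
  off reverts both.

These fixtures emulate the *contracts* of the computation — pair sets,
derivatives, spectra, geometric criteria, replay determinism — not real
molecular structure: clouds have no bonded topology or secondary structure,
the mini force-field table is synthetic, and ensembles are exactly Gaussian.
Passing tests therefore demonstrate correctness of the numerics and
plumbing, not docking accuracy on real complexes, which additionally needs
a real force-field table and an MD-derived eigenmodel.

Problem sizes in the test and acceptance runs (50–200-atom clouds, 5000
frame ensembles, 0.375 Å grids over single-atom and two-atom systems,
100-move sessions) were chosen to exercise every code path at interactive
scale; all of them complete in seconds on one CPU.

## Known limitations

* The ligand is rigid; receptor flexibility is linear-response only, so
  large, anharmonic rearrangements outside the retained subspace are not
  represented.
* Intramolecular (bonded) energetics are out of scope: relaxation balances
  ligand forces against the covariance-model restoring forces only.
* Hydrogens are used as given; no placement or optimization.
* The SES construction matches the true surface to grid resolution on
  re-entrant patches (analytic accuracy on contact patches); it is a
  distance-transform approximation, not an exact analytic SES.
* The distance-dependent permittivity slope, the force-collision threshold
  and the donor/acceptor map are field-standard defaults, not values with a
  canonical literature source; all are configurable and logged.
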