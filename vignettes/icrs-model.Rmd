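---
title: "A 2D finite-element model of intracorneal ring segment implantation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A 2D finite-element model of intracorneal ring segment implantation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corneafem)
```

`corneafem` simulates the refractive effect of intracorneal ring segments
(ICRS) — arc-shaped rigid implants inserted into a stromal tunnel to flatten
a keratoconic cornea — with a two-dimensional finite-element model of the
corneal meridional section.  This vignette is the package's own account of
the model: what is computed, which assumptions and parameters drive it,
which numerical choices were made where the design was genuinely open, and
what the verification suite does and does not establish.

## The mechanical model

### Geometry

The cornea is the band between two circular arcs with centers on the apex
axis: anterior radius 7.8 mm and posterior radius 6.4 mm, close to the
Gullstrand--LeGrand schematic eye, separated by a central thickness of
550 um (450 um for the thin, keratoconus-representative variant).  Because
the radii differ, the band thickens from apex to limbus, as the real cornea
does.  Through-thickness directions follow the anterior surface normal, and
"depth" always means distance from the anterior surface along that normal.

Three layers are carried: epithelium, anterior stroma and posterior stroma.
Several geometric parameters are free parameters of the model; their
defaults were chosen once on anatomical grounds and are configurable:

* epithelium thickness `t_epi = 50` um (standard anatomical value);
* anterior-stroma share `f_anterior_stroma = 0.4` of the stromal thickness,
  consistent with the two-layer picture in which the anterior stroma is the
  stiffer lamellar bed;
* corneal half-chord `half_chord = 5.8` mm (an ~11.6 mm corneal diameter).

The stromal tunnel that receives the ring is an 800 x 30 um rectangle whose
anterior edge sits at 70% of the local thickness.  Whether "70% depth" is
measured vertically or along the surface normal is ambiguous in principle;
the package measures it along the normal, consistent with the rest of the
through-thickness construction.  The tunnel's radial position is likewise a
free parameter of the model; the default places its center 3.0 mm from the
apex axis (a ~6 mm optical zone, typical for ICRS surgery).

### Mesh

The section is meshed with 8-node serendipity quadrilaterals on a
structured grid: columns are meridional stations, rows follow the layer
interfaces and the tunnel band.  All nodes — midside nodes included — are
placed by the exact geometric mapping, so surface nodes lie on the true
arcs.  The default density gives 64 x 6 = 384 elements in the axisymmetric
half-section, a deliberately coarse structural-mesh budget typical of this
model class; rather than prescribing one particular node layout, the
package targets the element budget and demonstrates mesh convergence
(the apex displacement under IOP changes by less than 1% when every
density count is doubled; see `test-mesh.R`).  The 30-um tunnel band is
always one element thick, so "doubling the density" multiplies the element
count by slightly less than four.

Stiffness is integrated with a 3x3 Gauss rule and stresses are recovered at
the 2x2 points, standard quad-8 practice.

### Material model

Each stromal layer is transversely isotropic in local spherical axes: the
radial axis runs through the thickness, and the plane of isotropy is
spanned by the two circumferential directions (the meridional tangent and
the hoop/out-of-plane direction).  The compliance, in Voigt order
(rr, cc, zz, rc) with engineering shear, is

$$ S = \begin{pmatrix}
 1/E_r & -\nu_{rc}/E_r & -\nu_{rc}/E_r & 0 \\
 -\nu_{rc}/E_r & 1/E_c & -\nu_{cc}/E_c & 0 \\
 -\nu_{rc}/E_r & -\nu_{cc}/E_c & 1/E_c & 0 \\
 0 & 0 & 0 & 1/G_{rc}
\end{pmatrix}, $$

with the reciprocal ratio $\nu_{cr} = \nu_{rc} E_c / E_r$ implied by
symmetry.  Positive definiteness of the inverse is checked at construction.
The default constants (kPa) are:

| layer | $E_r$ | $E_c$ | $G_{rc}$ | $\nu_{cc}$ | $\nu_{rc}$ |
|---|---|---|---|---|---|
| epithelium (isotropic) | 0.1 | 0.1 | $E/2(1+\nu)$ | 0.4 | 0.4 |
| anterior stroma | 500 | 1000 | 20 | 0.34 | 0.34 |
| posterior stroma | 400 | 800 | 16 | 0.34 | 0.34 |

One reading deserves a note: the posterior radial-circumferential Poisson
ratio is sometimes quoted with a negative sign for stromal tissue.  A
negative value is physically unmotivated here, so the package default is
+0.34, with the literal negative value available through
`default_materials(posterior_nu_rc = -0.34)` for sensitivity checks.

In the axisymmetric mode the zz slot is the hoop direction; in plane strain
it is the suppressed out-of-plane direction (the corresponding strain row
is identically zero, which condenses the operator without losing the
out-of-plane stress for von Mises recovery).

### Loads: IOP and stored pre-strain

The intraocular pressure, 15 mmHg = 1.99983 kPa (x 0.133322 exactly), acts
on the posterior surface as a consistent edge load along the inward normal
of the undeformed surface (dead load, consistent with the linear solve).

The stromal layers carry a layer-wise pre-strain: 0.015 in the anterior
stroma (radially compressive, circumferentially tensile) and 0.010 in the
posterior stroma (tensile in both).  The package interprets this as a
*stored* initial strain: the meshed geometry is the in-vivo, IOP-loaded
state, and the pre-strain is the strain that state already carries.  The
stress is therefore $\sigma = D(\varepsilon + \varepsilon_0)$ and the load
contribution is $-\int B^T D \varepsilon_0 \, dV$.  Two consequences favor
this reading over the thermal-expansion analogy (which differs only in the
sign of $\varepsilon_0$'s effect): the membrane carries tensile
circumferential stress of order $pR/2t \approx 13$-18 kPa, as a pressurized
shell must, and the pre-operative solve moves the apex by only tens of
micrometres, i.e. the imaged geometry is (approximately) the equilibrium.
Under the opposite sign the shell is hoop-compressed, inflates by ~0.2 mm
and sits near a structural instability.  One corollary: under biaxial
tension the *total* radial strain is negative in both stromal layers
(Poisson thinning), slightly more so anteriorly.

Because the reference state is pre-stressed, the linearization includes the
initial-stress (geometric) stiffness
$K_g = \int (\nabla N_a \cdot \sigma_0 \nabla N_b) I \, dV$ built from the
stored stress $\sigma_0 = D\varepsilon_0$ (plus the axisymmetric hoop
term).  This is a one-shot linear solve, not an incremental loop; it makes
transverse motion feel the membrane tension.  It can be disabled with
`solve_static(..., stress_stiffening = FALSE)`.

### Boundary conditions and constraints

The limbal edge is pinned (both translations fixed).  A 2D continuum node
carries no rotational degree of freedom, so pinning is the natural
rendering of "rigidly fixed with the possibility to rotate"; a variant that
couples the limbal edge as a rigid body hinged at its centroid was
implemented and produced indistinguishable results, so the simpler pinned
form is the default.  On the apex axis the axisymmetric mode enforces zero
radial displacement (symmetry).

Rigid bodies (the ring outline) are multi-point constraints tying a node
set to one master with two translations and one linearized rotation; any
master component may be free or fixed.  When the rotation is free, slave
positions are recomputed with the exact finite rotation after the solve, so
pairwise distances within the set are preserved to machine precision.
Constraints are applied by a sparse affine transformation
$u = u_p + Tq$, and the reduced symmetric system is solved directly.

## The in-silico implantation

The procedure mirrors the three-stage surgical emulation:

1. **Pre-op.** Solve the uncarved mesh under IOP and pre-strain.
2. **Carve and impose.** Deactivate the tunnel elements.  Map every tunnel
   node within the ring's footprint onto the triangular cross-section of
   the ring at the chosen arc angle, and bind the mapped boundary outline
   as a rigid body.
3. **Release and re-solve.** Free the rigid master's axial (y) translation
   so the ring finds its own equilibrium depth under IOP and pre-strain;
   its radial station and orientation are retained from the imposition.

The ring design carries linear thickness and base-width profiles over its
160 deg arc (150 to 300 um and 600 to 800 um for the default asymmetric
design; the 80 deg midpoint gives 225/700).  The triangular cross-section
is imposed as a *straight-edged* triangle in the meridional plane, in the
tangent/normal frame of the tunnel center: the implant is rigid PMMA, so
its cross-section does not bend with the corneal curvature, and the flat
base locally replaces the curved tunnel floor — which is precisely how a
stiff inclusion flattens the overlying shell.  Nodes keep their tangential
station under the mapping (the ring does not drag tissue along the
tunnel); where the base is narrower than the 800-um tunnel the remaining
void is left free, and where a base would exceed the tunnel width the
extra width is taken up entirely on the inner (axis-facing) edge, the
location that sees the highest radial tension during insertion.

Two honest consequences of displacement imposition are worth noting.  A
degenerate (vanishingly thin) ring still closes the 30-um tunnel void and
presses the floor to its chord, so the "zero implant" limit registers a
small local curvature blip (a few dioptres at the tunnel, under 1 D
centrally) rather than exactly zero.  And since no contact search is
performed (a deliberate non-goal), a ring narrower than the tunnel leaves
an open slot whose edges are free.

## Curvature analysis

The anterior surface (pre- or post-operative) is resampled and fitted with
a smoothing spline; exact normals come from the spline.  Sagittal (axial)
power at radial station $x$ is $(n-1) \cdot 1000 / r_{ax}$ dioptres, where
$r_{ax}$ is the distance from the surface point along the normal to the
apex axis; at the apex the limit $1/|y''|$ is used.  Flattening (radius
increase) is negative.  Defaults, each configurable:

* keratometric index $n = 1.3375$ (clinical convention; the power of a
  7.8 mm surface is then $337.5/7.8 = 43.27$ D).  The physical index 1.376
  is an accepted alternative and shifts powers by ~11%.
* evaluation grid: 25-um spacing across the central 10-mm zone;
* smoothing penalty $\lambda = 10^{-7}$.  The penalty must filter
  oscillations below the surface-node spacing (~50-100 um), where the
  piecewise-quadratic FE surface aliases the pointwise extremum of the
  change map, while leaving the analytic-circle recovery bias far below
  the 0.01 D gate; $10^{-7}$ is the smallest value that does both, and the
  gate holds across radii 5-10 mm.

In the plane-strain model the sagittal construction is ill-conditioned
within 1 mm of the apex (the surface is not axisymmetric there), and the
central zone is replaced by a natural-cubic interpolation across the gap,
supported by 2.5 mm of flanking data; the interpolation reproduces linear
profiles exactly.

The best-fit sphere of a zone (default 10 mm diameter) is the algebraic
least-squares (Kasa) circle fit, which recovers exact circles to machine
precision and is invariant to point ordering and mirror reflection.

Change maps are `post - pre` on the common grid.  Summaries per run:

* **central**: the change at the apex;
* **zone mean**: the mean change over the central 4-mm-diameter zone.  The
  "difference across the central optical zone" between two runs is the
  difference of their zone means; among the candidate formalizations
  (apex value, pointwise extremum, zone mean) the zone mean is the most
  stable, and the apex value is exposed separately;
* **peripheral**: the most negative change within the ring zone, the
  tunnel footprint widened by 1 mm on each side (1.6-4.4 mm radially); in
  plane strain only the implanted side is searched.

## The study and its problem sizes

`run_study()` executes the four designs (asymmetric, thickness-only at
700 um base, base-only at 225 um thickness, symmetric 225/600) at the 0,
80 and 160 deg stations in both mechanical modes on the 550-um cornea,
plus the asymmetric design on the 450-um cornea axisymmetrically — 27 runs.
Pre-operative solves are shared per (mode, cornea).  At the default density
(384 elements axisymmetric, 768 plane strain) the full study takes about a
minute on one CPU; there is no randomness anywhere, so the result table is
bit-reproducible.  Sensitivities to thickness and base width are
least-squares slopes of the flattening magnitudes across the three-station
sweeps, averaged over the central and peripheral summaries (an
endpoints-only variant is available as a flag).

## Verification, and what it does and does not show

The solver is verified against independent closed forms: the quad-8 patch
test (uniform stress on distorted anisotropic meshes, both modes, machine
precision), Lame thick-sphere and thick-cylinder pressure solutions (<1% at
modest density, converging under refinement), rigid-body null space,
exact-circle curvature recovery, global equilibrium residuals below 1e-8,
exact linearity, and rigidity of the constrained ring outline to 1e-9 mm.
These establish that the discretization, constraints and post-processing
do what they claim.

They do not establish clinical accuracy, and one structural limitation
matters when comparing with published dioptre values for this procedure.
The model is small-strain and linear: the imposed ring displacement
(up to 300 um against a 550-um-thick shell) produces a strong, strongly
localized response — peripheral flattening of tens of dioptres above the
ring with steepening just outside it, growing with ring thickness and
dominating the base-width effect, and about half the bilateral effect in
the unilateral plane-strain bound — but it transmits little of the
insertion to the apex, so central and whole-surface (best-fit-sphere)
changes remain at the sub-dioptre level.  Published results from
large-deflection solvers report central flattening of the same order as
the peripheral extremes; reproducing that requires finite-rotation
kinematics, which is outside this package's scope (an updated-Lagrangian
loop is a documented non-goal).  The package therefore reproduces the
local/peripheral quantities and the qualitative orderings, while central
metrics should be read as the linear lower bound of the response.  The
initial-stress stiffening term narrows, but does not close, that gap at
physiological membrane tensions.

## Degenerate inputs and tie-breaks

* Zero loads return the exact zero solution; assembling a carved mesh
  ignores inactive elements, and nodes orphaned by carving are pinned (or
  given their imposed positions) so the system stays nonsingular.
* Carving twice warns and is a no-op; imposing on an uncarved mesh errors.
* Collinear points make the sphere fit error out; a curvature grid wider
  than the surface data errors rather than extrapolating.
* The peripheral extremum reports the grid point of the most negative
  change; exact ties resolve to the innermost grid point by `which.min`.

## Reproducing the numbers

`scripts/acceptance.R` (repository root) re-runs the relevant simulations
from scratch with the installed package and writes the headline quantities
as JSON; the README describes the invocation.  The test suite
(`tests/testthat/`) contains the verification gates above plus
property-style checks of the study-level orderings.
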