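---
title: "ventmesh: models, numerics and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ventmesh: models, numerics and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the geometric model, the numerical methods, the tunable parameters and
their defaults, what the synthetic phantoms do and do not establish, and
the places where the design was genuinely open and a choice had to be
made. It states no empirical result that the test suite does not itself
compute.

## 1. The mesh model

The ventricular wall is represented by a structured hexahedral mesh with
tricubic Hermite interpolation. Each node carries, per coordinate, eight
degrees of freedom (DOFs): the position, the three first derivatives with
respect to the element-local coordinates, the three mixed second
derivatives and the mixed third derivative. Within an element the geometry
is the tensor product of the 1-D cubic Hermite shape functions

$$h_{00}=1-3\xi^2+2\xi^3,\quad h_{01}=3\xi^2-2\xi^3,\quad
  h_{10}=\xi(\xi-1)^2,\quad h_{11}=\xi^2(\xi-1),$$

so the two value functions form a partition of unity and the basis
reproduces affine maps exactly (tested to 1e-10). Local coordinates map to
anatomy: $\xi_1$ circumferential (periodic by node sharing), $\xi_2$
longitudinal from apex to base, $\xi_3$ transmural from endocardium to
epicardium.

**Derivative scale factors.** Derivatives are taken with respect to *unit*
element-local coordinates (unit scale factors). Because the template
parameter spans are uniform per direction, DOFs shared between adjacent
elements are consistent; arc-length scale factors are a possible extension
but are not implemented.

**Collapsed apex.** The apex ring nodes are distinct storage entries
constrained to a common position ("tie groups"). The Jacobian is singular
exactly on the collapsed face; all quadrature is at strictly interior
Gauss points (default order 4 per axis, configurable), which keeps every
integral and the Jacobian-ratio quality metric finite. An apical-hole
variant is available (`apex_style = "hole"`); the squared-patch apex
topology is not implemented.

## 2. Template synthesis

Templates are shells between two coaxial truncated ellipsoids (inner
semi-axes = outer − wall thickness), cut flat by the basal plane at the
$\xi_2 = 1$ face, with per-layer polar angle limits chosen so every
transmural layer ends on the same plane (a flat base suits mechanical
boundary conditions and avoids thin skewed valve elements).

**Volume-equalizing parameterization.** With uniform parameter spacing the
volume differential det J varies strongly inside ideal-template elements:
transmurally because the layer area grows outward (for a one-element wall
the inner/outer ratio alone caps the Jacobian ratio near 0.45) and
longitudinally because of the $\sin\theta$ factor towards the apex. Both
directions are therefore reparameterized so det J is near-constant per
unit parameter: the transmural coordinate inverts the cumulative
layer-volume weight $(a_{in}+ts)(b_{in}+ts)(c_{in}+ts)$ (closed form,
inverted by a monotone spline), and the longitudinal coordinate inverts
$(1-\cos\theta)+\delta\,\theta$ — the spherical equal-area profile
regularized by $\delta = 0.2$ because pure equal-area has a square-root
singularity at the apex that would blow up the derivative DOFs. With
these profiles every non-apex element of an ideal template has Jacobian
ratio above 0.5 at the cohort configurations (asserted). Nodal DOFs are
derived from the analytic parameterization by central finite differences
(steps 1e-5 / 1e-4 / 2e-3 for first / second / third derivatives) — the
map is analytic in all parameters, slightly outside $[0,1]$ included, so
central stencils are valid everywhere; the quadrature volume of an ideal
template agrees with the closed-form shell volume to 0.1%-level (asserted
at 1%).

The BiV template adds an RV free wall lifted off the LV epicardium along
the exact ellipsoid normal by a smooth bulge
$d\,\sin(\pi s)\sin(\tfrac{\pi}{2} t)$ that vanishes on the squared
insertion line (two meridional sides and the bottom); the inner surface
uses the smooth offset $b^2/(b+\tau)$ which approaches (bulge − wall
thickness) inside and collapses to zero at the insertion. Insertion nodes
coincide with LV epicardial nodes to machine precision and are
position-tied to them. Sharing *full* DOF sets across the insertion would
force the free wall to leave the epicardium tangentially, which is
geometrically wrong — hence position ties only. The squared insertion is
anatomically imperfect near the RV apex; this is a known limitation of the
structured BiV topology, retained deliberately.

**Tailoring.** From the shape descriptor the template copies: in-plane
cavity semi-axes (sqrt(5) x sd of the pool coordinates — exact for a
uniform solid ellipsoid) plus wall thickness for the outer radii; the
long-axis extent and the long-axis station of maximal width (equator) for
the long semi-axis and base height; RV pool extents, insertion level
(RV/LV long-axis extent ratio) and angular span for the RV free wall. The
RV wall thickness is not separately measurable from a single binary mask
and defaults to max(0.35 x LV thickness, 1.5 mm).

## 3. Shape analysis

* *Pools and valves.* The cavity is the convex-hull fill of the mask minus
  the myocardium. True 3-D hull libraries are not among the dependencies;
  the fill iterates slice-wise 2-D convex hulls along all three axes to a
  fixed point, which is exact for ellipsoid-like shapes and a documented
  approximation otherwise. Components are separated, when bridged, by
  adaptive erosion (6-connected Euclidean ball, radius grown until two
  significant components appear) followed by label spreading. The LV is
  the pool with the larger volume-to-surface ratio (more convex), ties
  broken by volume. Valve voxels are cavity voxels touching the hull
  boundary *and belonging to a main pool* — the pool restriction matters
  because the hull also bridges the concave notch along the RV insertion,
  which is not an opening.
* *Basal plane.* Total-least-squares plane through the valve voxel
  centres (smallest principal component), normal oriented away from the
  myocardial mass. For sparse slice stacks the normal is snapped to the
  slice normal: with a handful of coarse slices the TLS normal is
  unreliable, and for such acquisitions the long axis is the slice normal
  by definition anyway.
* *Axes.* Long axis = basal-plane normal (slice normal when
  `data_slices` is set); left-right axis = in-plane projection of the
  LV-to-RV centroid vector, or, for LV-only masks, the larger in-plane
  principal inertia axis (needed so anisotropic scaling is defined); the
  third axis completes a right-handed orthonormal frame, which also
  guarantees the initial affine has positive determinant.
* *Wall thickness.* No standard estimator exists for a single binary
  mask, so one had to be chosen. Dense masks use a distance-transform ridge: twice the 95th
  percentile of the Euclidean distance-to-background over the myocardium
  (the distance distribution over a shell of thickness $t$ rises to
  $t/2$; the high quantile reads the ridge robustly). Sparse stacks use
  the in-plane difference between foreground and cavity half-widths on
  the RV-free side: the 3-D ridge is corrupted there by the apex cap
  slice and the coarse axial spacing.
* *Sparse long-axis geometry.* The axial extent of a sparse stack is
  quantized by the interslice distance. Since in-plane widths are
  accurate on every data slice and an ellipsoid's squared width is
  quadratic in the axial coordinate, the long semi-axis, apex position
  and equator station are recovered by a quadratic fit of width² over the
  data slices (with a half-gap fallback when fewer than four foreground
  slices exist).

## 4. Registration

The registration engine referenced by the original pipeline is a
proprietary black box; this package substitutes a functionally equivalent
multi-pass control-grid registration that honours the stated contract —
the LoD schedule and a dense displacement field:

* LoD $k$ runs $k$ passes with control-node spacings the first $k$ of
  (10, 8, 6, 4, 2) voxels ("first-k" reading of the schedule; an override
  `node_spacings` is exposed).
* Per pass, displacements live on a regular control lattice interpolated
  to voxels by trilinear tents; the cost is the sum of squared
  differences between Gaussian-smoothed (sigma = 1 voxel) binaries plus a
  second-difference smoothness penalty with weight
  `reg_weight * n_domain / n_control` (default `reg_weight = 0.05`,
  calibrated once so that the identity case stays below 0.1 voxel and a
  3-voxel translation is recovered within 0.5 voxel — both asserted in
  the suite).
* The optimizer is deterministic gradient descent with backtracking line
  search and heavy-ball momentum (restarted whenever a step would
  increase the cost); passes warm-start by resampling the previous
  control field.
* The problem is solved in *fixed-image* (target) space — $w$ maps target
  points to template points — because the sparse-slice domain restriction
  lives on target slices and a forward-space formulation would let the
  optimizer push the template into the null slices. The returned field
  $u$ (template to target, the convention every downstream consumer uses)
  is the fixed-point inverse of $w$ (10 iterations; fields are smooth and
  the iteration converges rapidly). The field is tapered to zero outside
  a configurable band (default 15 voxels) around the union foreground;
  values outside the grid clamp to the boundary.
* Sparse stacks: the similarity is evaluated only on data-slice voxels,
  and the *fixed* image is smoothed in-plane only — smoothing across the
  null slices would dilute the data slices' intensities far below the
  moving image's and bias the match.

Rasterization of a mesh (for the moving image) subdivides the external
surface into triangles and voxelizes by vertical ray parity with a fixed
sub-voxel ray offset to avoid shared-edge double counts; it agrees with
the analytic phantom inside-test on more than 98% of voxels and with the
quadrature mesh volume to 2%.

## 5. Variational warping

The displacement field is projected onto the mesh DOFs by weighted linear
least squares over element Gauss points (weights = Gauss weights x det J,
i.e. the volume-weighted L2 norm of the projection error), assembled as
sparse normal equations per coordinate. Tied nodes share one position
unknown, so the collapsed apex and the RV insertion stay watertight by
construction. Field values at Gauss points come from trilinear
interpolation of the voxel field.

**Regularization.** A plain mean-scaled (trace-scaled) Tikhonov ridge was
found to distort the apex mixed-derivative DOFs, whose quadrature support
is ~1e-8 of the average diagonal — it broke exact affine reproduction by
orders of magnitude. The implemented ridge is *relative*: each diagonal
entry is inflated by `eps * max(diag, floor)` with default
`eps = 1e-13`, and the floor escalates (1e-12, 1e-6, 1e-2 of the mean
diagonal) only if the factorization actually fails. Affine fields are
then reproduced to better than 1e-8 (asserted), and genuinely singular
systems still solve.

## 6. Quality, accuracy, success

* *Jacobian ratio.* $Q^e = \min_i \det J_i / \max_i \det J_i$ over the
  element's interior Gauss points; 1 for affine elements, 0 reported
  (with an inversion flag) if any det J is non-positive.
* *Aggregate quality and the 0.33 threshold.* Both the minimum and the
  mean of $Q^e$ are reported, but the success criterion uses the **mean**:
  with collapsed apex elements the minimum is structurally ~0.005
  (det J vanishes towards the degenerate face at any quadrature order),
  so a 0.33 threshold on the minimum would be unsatisfiable for this
  topology, while reported per-mesh qualities in the literature (~0.37)
  are only consistent with the average Jacobian ratio.
* *Fitting error.* For a binary image the 0.5-level marching-cubes
  vertices are exactly the midpoints of grid edges joining foreground and
  background voxels; that vertex set is computed directly (the
  triangulation is irrelevant to point-to-surface distance). Each vertex
  is matched to the closest point of the mesh's external surface: seeded
  by nearest neighbour on an 8x8-subdivided surface, refined by damped
  Gauss-Newton in the face parameters (max 50 iterations, tolerance
  1e-8, step clamp 0.25, fallback to the seed on divergence). The vertex
  mean and max are the headline numbers; a surface-Gauss-quadrature-
  weighted mean (distance from surface Gauss points to the isosurface) is
  also reported, covering both readings of a surface-integrated error.
* *Success.* mean error strictly below the voxel diagonal AND mean
  Jacobian ratio at or above 0.33 (strict/inclusive boundary conventions
  asserted in the suite).
* *Transmural linearization.* For every transmural node column the
  $\xi_3$ derivative is *re-pointed* along the straight chord between the
  opposite wall nodes while preserving the node's transmural speed (its
  component along the chord); the $\xi_3$-mixed derivatives become the
  chord differences of the in-surface derivatives scaled by the relative
  speed (chain rule). Node lines are exactly straight afterwards —
  mid-parameter points lie on the chord to 1e-8 — though not uniformly
  parameterized: a uniform chord/n replacement would undo the template's
  volume-equalized transmural parameterization and lower quality by
  construction. DOFs not involving $\xi_3$ are bit-identical afterwards,
  so the endocardial and epicardial surfaces are exactly preserved (the
  flat base annulus, which does depend on radial derivatives, may flatten
  slightly — the source of the tiny accuracy change). The operation is
  idempotent and leaves an ideal template essentially unchanged (its
  transmural lines are already straight). **Known negative result:** on
  this pipeline's warped meshes the linearization is a near-no-op for
  quality (mean Jacobian ratio changes by −0.003..+0.001 per case), not
  the distinct improvement the reference pipeline reports. That gain
  presupposes crooked transmural derivatives left by the warping step;
  the L2 projection under a smooth tent-interpolated field already
  yields near-straight transmural lines, leaving nothing to recover. The
  corresponding acceptance assertion (quality non-decreasing in every
  case) is intentionally left failing rather than weakened; the step
  remains in the pipeline because it is cheap, surface-preserving, and
  the correct guard for rougher fields.

## 7. The phantom world

Phantoms are truncated-ellipsoid shells with an analytic inside test — no
mesh rasterization is involved, so they are an independent oracle for
every stage. Defaults describe a normal adult LV at end diastole: outer
semi-axes (33, 33, 52) mm, 10 mm wall, base plane at 35% of the long
semi-axis above the equator; the BiV variant adds a 4 mm RV shell as a
laterally offset ellipsoid crescent. Deformations are restricted to
analytic invertible maps (affine; sinusoidal bumps inverted by fixed
point), so the true displacement is known exactly anywhere. Sparsification
keeps slices at the stated 4–20 mm distances and zeroes the rest;
slice-shift artifacts translate single slices in-plane. Cohorts are seeded
and RNG-isolated.

What a green phantom test does *not* establish: robustness to papillary
and trabecular detail, segmentation noise, non-ellipsoidal disease
remodelling, or multi-label inputs. The phantom family is deliberately the
geometry the template can represent well; the cohort experiment therefore
probes the *pipeline* (analysis, alignment, registration, projection), not
anatomical generality.

## 8. Scaled-down acceptance experiments

The acceptance criteria run end to end on one CPU inside a tight test
budget; phantom sizes use compact but realistic ventricles (cohort at
1.5 mm, sparse experiments at 1.4 mm isotropic; the self-fit criterion at
the stated 1 mm). Scaling is in problem size only — success-rate, error
and quality thresholds are asserted exactly as stated. The sparse-data
experiment averages two BiV anatomies, mirroring the two-average-anatomy
protocol of the original sparse-performance experiment, which also damps
slice-phase discretization noise.

## 9. Known limitations

* Squared RV insertion line (anatomically wrong near the RV apex).
* Axis-aligned grids only: direction matrices must be pre-applied.
* The hull fill is slice-wise convex, not a true 3-D hull.
* No arc-length Hermite scale factors, serendipity elements, fibre
  fields, valve planes, atria or four-chamber topology.
* Registration offers no diffeomorphic guarantee; extreme LoD 5 fits on
  coarse masks can fold elements (reported as zero quality with an
  inversion flag rather than hidden).
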