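---
title: "Models and methods behind mammoplan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mammoplan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mammoplan implements a complete consultation-planning loop for breast
augmentation: silhouette-based 3D torso reconstruction, voxel-based elastic
implant simulation, and surface-distance quality control. This vignette
explains the models, the parameters that matter, the numerical choices, and
what the synthetic evaluation does and does not establish. Everything runs
in one patient coordinate frame: +x patient-left, +y cranial, +z anterior,
units millimetres.

## The torso template

Both the phantom generator and the reconstruction share one surface
parametrization. The chest is a stack of superellipse cross-sections

\[ |x/a(y)|^{n} + |z/b(y)|^{n} = 1 \]

with per-height semi-axes \(a(y), b(y)\) linearly interpolated between
control heights and a common exponent \(n\) (default 2.5, between an ellipse
and a rounded box; the silhouettes do not constrain \(n\), so generator and
fit use the same fixed value). Each breast is a half-ellipsoid height field
over a base disk on the anterior chest wall — base centre \((c_x, c_y)\),
base radius \(r\), projection \(p\) — displaced anteriorly and sheared
caudally by the ptosis offset (implemented as a fixed-point evaluation of
the sheared field, three iterations; a pure shear, so breast volume is
preserved). Two smoothing choices keep the geometry well behaved:

* the fold: the displacement eases in as a cubic below the blend width
  (default 5 mm), so the inframammary fold merges tangentially with finite
  curvature while the added volume still integrates to the half-ellipsoid
  value \( \tfrac{2}{3}\pi r^2 p \) to within a few percent;
* the lateral wrap: the displacement is tapered by a smoothstep of the
  anterior chest height (15 mm scale) so the breast base fades around the
  side of the chest instead of ending in a cliff.

Meshing sweeps rings between the caudal and cranial ends and closes both
with flat fan caps. Quads are split along their *shorter* diagonal: besides
better-shaped triangles, this rule is mirror-covariant, so a bilaterally
symmetric template produces an exactly mirror-symmetric surface (a uniform
diagonal would not — its mirror is the anti-diagonal).

## What the phantom emulates

`generate_torso()` stands in for a patient visit: it renders orthographic
binary silhouettes of the ground-truth mesh in the three views (front along
−z, laterals along ±x, exactly 90° apart), projects the true anatomical
landmarks into each view with seeded Gaussian annotation jitter (default
2 px), and emits the two exact tape measurements (nipple-to-nipple,
nipple-to-fold). Defaults describe an average build: chest width 300 mm,
depth 200 mm, torso height 400 mm, breast base diameter 120 mm, projection
50 mm, ptosis 10 mm, bilateral symmetry, 1 mm/px image scale, with a fixed
mild waist profile.

The phantom deliberately idealizes several things real photographs do not:
projection is orthographic (no perspective), the background is perfectly
clean (contours are noise-free; only the landmarks are jittered), arms and
hair never occlude the torso, and the chest sections are front/back
symmetric. Passing the end-to-end error bounds on phantoms therefore
demonstrates that the *algorithmic* chain — calibration, contour handling,
fitting, registration, distance protocol — is correct and stable under
annotation noise; it does not certify accuracy on clinical photographs,
where contour extraction and perspective would add error sources that are
absent here.

## Reconstruction

`reconstruct_patient()` composes four stages.

1. **Calibration.** Frontal scale = nipple-to-nipple (mm) over the nipple
   pixel distance; lateral scales = nipple-to-fold over the corresponding
   pixel distance. Coincident landmarks raise a degenerate-calibration
   error; scales disagreeing by more than 3× are rejected as a landmark
   sanity check.
2. **Contours.** The image is thresholded (Otsu for grayscale, with the
   polarity chosen so the landmark centroid is foreground), the connected
   component containing the landmarks is kept, and its boundary is traced as
   the 0.5-level contour of the padded binary mask — a closed, sub-pixel
   polyline.
3. **Breast typing.** From the lateral profile between notch and fold:
   maximum projection depth (anterior bulge beyond the chest wall, using the
   observable posterior half-depth as the chest reference), signed nipple
   drop versus the fold, and the count of curvature extrema. Labels: flat if
   depth < 15 mm, ptotic if drop < −10 mm, else normal (thresholds in
   `breast_type_config()`); the label selects the initial projection and
   ptosis of the fit.
4. **Template fitting.** Stage one reads \(a(y)\) from frontal scanline
   widths and \(b(y)\) from lateral scanlines (section centreline estimated
   from the upper chest, where the anterior silhouette is pure chest wall),
   then fits each side's \((c_y, r, p, \text{ptosis})\) by bounded
   finite-difference least squares (`nlminb`, iteration cap 500, relative
   tolerance 1e-6) on the dense anterior lateral profile. Two weak priors —
   the frontal nipple height observes \(c_y - \text{ptosis}\) and the
   frontal fold height observes \(c_y - r\) — resolve the otherwise soft
   trade-off within that parameter trio. Stage two polishes the breast
   parameters by coordinate descent (steps 3/3/2/2 mm halved over four
   sweeps) on the mean squared nearest-point distance between the
   template's projected contours and the extracted contours plus the same
   landmark terms; only strictly improving steps are accepted, so the
   per-side objective trace is monotone by construction.

Two design points deserve emphasis.

*Scale fusion.* The lateral views are first rescaled through cross-view
consistency of the torso silhouette height (the frontal scale rests on the
long nipple-to-nipple baseline, whereas the nominal lateral scale divides a
short, doubly jittered segment). After stage one, the residual global scale
is re-estimated by an inverse-variance (pixel-baseline-squared) fusion of
three redundant observations: the nipple baseline, the fold-to-fold
baseline (the folds lie at the same ±x as the nipples), and per side the
nipple-to-fold measurement against the fitted template's own 3D
nipple-to-fold distance, which rests on jitter-free contours. The frame is
rescaled once and stage one repeated. Without this fusion, the scale noise
of two jittered nipple clicks propagates multiplicatively into every
reconstructed length and dominates the surface error.

*Per-side refinement.* Each orthographic lateral silhouette is the union of
both breasts, so with near-symmetric anatomy the smaller side's parameters
are unconstrained by the union alone. The refinement therefore evaluates
each side against a template with that side mirrored to both (keeping the
other centre-x), exactly as stage one does. The corollary is a genuine
limitation: for markedly asymmetric anatomy, each lateral silhouette is
dominated by the larger side and the smaller side is reconstructed slightly
too large.

## Voxelization and planning

`voxelize()` classifies voxel centres by ray-casting parity (rays along +z,
one per column, with a deterministic sub-voxel offset whose sign follows the
side of the grid centre so mirror-symmetric meshes classify symmetrically;
interpolated crossing heights are clamped to each triangle's z-range so
near-parallel sliver triangles cannot amplify roundoff). More than 0.1% of
odd-parity columns raises a non-watertight error. The interior is peeled
into shells by the euclidean distance transform of the outside mask (exact
squared EDT, separable lower-envelope passes), offset by half a voxel to
approximate distance to the surface: skin (default 5 mm), fat/gland (15 mm),
muscle (10 mm), bone/torso core innermost. These are effective,
consultation-scale layer thicknesses — thick enough to carry at least one
voxel layer at the default 4 mm spacing — not histological measurements.
Every tissue voxel touching OUTSIDE is skin by construction.

Implants are half-ellipsoids, semi-axes \(d/2, d/2\) (round) or
\(d/2, 0.85\,d/2\) (anatomical) and the nominal projection, uniformly
rescaled by bisection until the voxelized volume matches the nominal volume
within 2%. `create_pocket()` drapes the flat posterior face onto the local
interface of the chosen placement per column (bone/muscle for submuscular,
muscle/gland for subglandular and dual plane) and shifts each overlying
tissue column anteriorly by the implant thickness there: overlapped tissue
is displaced, never deleted, and the tissue voxel count is invariant.

## The tissue solver

`build_tem()` creates one particle per tissue/implant voxel. Constraints:

* stretch between 6-neighbours (rest length = spacing) and the 12 edge
  diagonals (spacing·√2), stiffness = mean of the endpoint tissues
  (defaults: muscle 2.0, fat/gland 0.6, skin 1.0 × elasticity multiplier;
  loose/moderate/tight/very-tight multipliers 0.5/0.75/1.0/1.3);
* a relaxed volume-restoration constraint per complete voxel cell, scaling
  the cell about its centroid toward the rest volume (scale factor clamped
  to [0.5, 2]);
* shape-memory bending on collinear skin triples (the midpoint is pulled
  toward the neighbour average plus its rest offset);
* implant particles are near-rigid (stiffness × 100) and anchored to their
  inserted pose (weight 50) — the prosthesis is stiff and sits against the
  chest wall;
* an implant–tissue exclusion constraint projects free tissue particles out
  of each implant ellipsoid (weight 10). This is the "make space for the
  implant" step: without it nothing prevents relaxing tissue from
  re-entering the implant volume.

`solve_tem()` projects all constraints with *Jacobi* accumulation
(stiffness-weighted averaging of all corrections, under-relaxation 0.8).
Jacobi converges more slowly than a sequential sweep but is
order-independent: the solve is bit-deterministic and exactly
mirror-symmetric for mirror-symmetric inputs, which a Gauss–Seidel ordering
would break. Termination: maximum per-iteration displacement below the
tolerance (default 0.05 mm, cap 800 iterations); growth over 50 consecutive
iterations aborts with a divergence diagnostic. A state with no violated
constraints does not move: the implant-free rest state is a fixed point.
Gravity is available as a constant per-iteration caudal displacement but is
off by default, both so the analytic checks remain exact and because no
measured loading data exists to calibrate it against.

The four elasticity classes act through the skin stretch/bending weights.
At consultation resolution the bulge apex is largely geometry-determined
(implant plus incompressible overlying stack), so tightness expresses
itself in the transition zone: tighter skin flattens the bulge shoulder,
and the upper quantiles of anterior skin height order accordingly
(loose ≥ very tight). The *direction* of this modulation — looser
skin admits the larger bulge — is a package design decision, chosen as the
clinically intuitive behaviour.

`extract_skin_surface()` splats particles back onto the lattice as an
occupancy mask, applies one morphological closing pass (to seal gaps opened
by stretched cells), builds the occupancy signed-distance field from two
EDTs, smooths it with a separable [1,2,1]/4 kernel (twice) to remove the
lattice staircase, and triangulates the 0.5-occupancy boundary by marching
tetrahedra on the body-centred 24-tet cube decomposition. That decomposition
(face centres + body centre) is invariant under axis reflections — the
classic 6-tet split is chiral and would bake a ~half-voxel left/right
asymmetry into every extracted surface. Interpolation parameters are clamped
to [1e-3, 1−1e-3] so no emitted triangle degenerates; triangles are oriented
along the per-tet affine field gradient, giving consistent outward normals
and hence signed volumes by the divergence theorem.

## Validation protocol

Registration is iterative closest point with point-to-surface
correspondences and a closed-form Kabsch update, strictly rigid — no
scaling, so the breast shape cannot be deformed toward the reference. The
rms against current correspondences is non-increasing by construction;
convergence is declared when the rms improvement falls below the tolerance
(default 1e-5 mm, cap 200 iterations; known-transform recovery to 0.1 mm /
0.1° needs the tighter 1e-7/500 used in the tests, because tangential
sliding decays geometrically). Meshes starting more than 200 mm rms apart
are flagged not-converged rather than chased.

Breast crops keep vertices within 1.2 × base radius of each nipple, bounded
medially by the sagittal plane through the sternum (the nipple midline);
faces survive iff all three vertices do. The headline metric is the
*directed* distance — for each vertex of the reconstruction, the unsigned
distance to the nearest point of the reference — summarized with
linear-interpolation quantiles (the convention is a package choice) and the
1.5·IQR whisker rule. The symmetric (two-sided) variant is available by
swapping the arguments but is not the headline number. Per-case box plots
and pooled-vertex summaries are both reported by the QC suite, since
either aggregation is defensible.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run at consultation scale: the
10-case phantom experiment uses the default 300 mm phantom at 1 mm/px and
4 mm reconstruction meshes; simulator checks voxelize at 4 mm spacing
(hundreds of thousands of particles, a few hundred Jacobi iterations);
analytic accuracy checks (sphere volume/area, implant volume) run at
0.5–2 mm. Unit tests use a compact 220 mm phantom where the full-size one
adds nothing. The noise-free parameter-recovery case renders at 0.5 mm/px,
because sub-percent parameter agreement is meaningless below the
rasterization quantum; agreement is asserted to 1% with a 0.5 mm absolute
floor for millimetre-scale parameters (ptosis), which is at the rendering
resolution limit.

## Known limitations

* Orthographic phantom views: real lateral photographs occlude the far
  breast; the orthographic union instead lets the larger breast mask the
  smaller one, biasing asymmetric reconstructions.
* The superellipse exponent is unidentifiable from silhouettes and fixed by
  convention; a patient whose cross-sections deviate strongly from the
  family will reconstruct with a biased mid-surface even when all
  silhouettes fit.
* Tissue layers are concentric shells of uniform thickness; no glandular
  anatomy, no rib geometry beyond the fixed core.
* The solver is quasi-static and elastic: no viscoelasticity, no
  gravity-loaded preoperative state, no capsular behaviour.
* Elasticity classes shift results by fractions of a millimetre at 4 mm
  voxel spacing; clinically meaningful elasticity contrast would need finer
  lattices and measured material constants.
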