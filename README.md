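# mammoplan

Quantitative tooling for breast-augmentation consultation planning. The
package reconstructs a patient-specific 3D torso surface from three ordinary
2D views (frontal plus both laterals) with a handful of clicked anatomical
landmarks and two tape measurements, simulates implant placement in a
voxelized, layered soft-tissue model, and validates reconstructed or
simulated surfaces against reference scans with a surface-distance protocol.
Because no clinical photographs or laser scans are distributable, a
parametric torso phantom generator provides fully synthetic, seeded
end-to-end test cases with known ground truth.

## The model

**Reconstruction.** The torso is parametrized as a stack of superellipse
cross-sections |x/a(y)|^n + |z/b(y)|^n = 1 (one half-width/half-depth pair
per control height, common exponent n) with one half-ellipsoid breast patch
per side — base centre (c_x, c_y), base radius r, anterior projection p and
a caudal ptosis shear — blended smoothly onto the anterior chest wall.
Image scales (mm/px) come from the two measurements: nipple-to-nipple
calibrates the frontal view and nipple-to-submammary-fold the laterals.
Body contours are extracted from the silhouettes, the per-height semi-axes
are read directly from contour scanlines, and the breast parameters are
recovered by bounded least squares on the anterior lateral profile followed
by coordinate descent on the projected-contour distance. The result is a
watertight triangle mesh in a fixed patient frame (+x patient-left,
+y cranial, +z anterior, mm).

**Simulation.** The torso is voxelized into anatomically ordered layers
(bone/torso core, pectoral muscle, fat and gland, skin). Implants are
half-ellipsoids (diameter, projection, volume taken from a catalogue CSV)
inserted at the planned interface — bone/muscle for submuscular, muscle/gland
for subglandular and dual plane — displacing, not deleting, the overlying
tissue. A relaxed-constraint tissue elastic model (one particle per voxel;
stretch, volume-restoration and skin-bending constraints projected
iteratively, with four clinical skin-elasticity classes modulating skin
stiffness) relaxes the tissue to equilibrium, and the postoperative skin
surface is extracted by marching tetrahedra.

**Validation.** A reconstruction is rigidly aligned to the reference surface
by ICP (strictly rigid, so breast shape is never deformed to flatter the
comparison), the breasts are cropped around the nipples, and the directed
per-vertex surface-to-surface distance (reconstruction → reference) is
summarized with box-plot statistics (1.5·IQR whisker rule).

## Worked example

```r
library(mammoplan)

# a synthetic patient: ground-truth mesh, three silhouettes, jittered
# landmark annotations, and the two exact measurements
spec <- torso_phantom_spec(seed = 7)        # 2 px annotation jitter default
case <- generate_torso(spec)
case
#> phantom_case (seed 7): mesh 20606 vertices; jitter sigma 2 px

# 2D -> 3D reconstruction from the three views
rec <- reconstruct_patient(case$silhouettes, case$landmarks, case$measurements)
rec
#> reconstruction_result: mesh 20810 vertices; breast type normal
#>   mean contour residual mm: front 1.83, left 0.50, right 0.68

# quality control against the ground truth (stands in for a laser scan)
reg <- rigid_register(rec$mesh, case$ground_truth)
reg
#> registration_result: rms 0.5973 mm after 96 iterations (converged)
crops <- crop_breasts(reg$moving_registered, case$nipples, spec$base_diameter / 2)
surface_distance(crops$left, case$ground_truth, side = "left")
#> distance_report (reconstruction -> reference, left): n = 788
#>   mean 0.31 | q1 0.06 | median 0.14 | q3 0.34 | max 3.00 mm
```

The mean directed error of the cropped breast is 0.31 mm against the known
ground truth at zero registration bias; across seeded phantoms with 2 px
annotation jitter the per-case means stay in the low millimetres (see the
acceptance section below). `autoplot()` on a distance report draws the box
plot; `tidy()`/`glance()` return per-vertex and one-row tibbles.

Implant planning and simulation:

```r
catalogue <- read_implant_catalogue(
  system.file("extdata", "implants_synthetic.csv", package = "mammoplan"))
filter_catalogue(catalogue, diameter = c(105, 115),
                 projection = c(35, 45), volume = c(180, 260))
#> # A tibble: 6 x 6   (RND-180-M ... ANA-240-M)

plan <- placement_plan(
  left  = list(implant_id = "RND-220-M", center = c(90, -180),
               placement = "SUBGLANDULAR"),
  right = list(implant_id = "RND-220-M", center = c(-90, -180),
               placement = "SUBGLANDULAR"))
sim <- simulate_augmentation(case$ground_truth, plan, catalogue)
sim
#> augmentation_result: implants 440 cc total, simulated gain 441 cc
#>   solver: 626 iterations, residual 0.04976 mm (converged)
write_mesh(sim$postop, "postop.obj")
```

The simulated breast-volume gain (441 cc) tracks the nominal implant volume
(2 × 220 cc) to within a percent here; the package's tests require 10%.

## Command line

A thin wrapper exposes the pipeline to the shell:

```sh
Rscript inst/cli/mammoplan.R phantom --out case/ --seed 3
Rscript inst/cli/mammoplan.R reconstruct --front case/front.png \
    --left case/left.png --right case/right.png \
    --annotations case/annotations.json --out recon/
Rscript inst/cli/mammoplan.R simulate --preop recon/reconstruction.obj \
    --plan plan.json --catalogue implants.csv --elasticity tight --out post/
Rscript inst/cli/mammoplan.R validate --recon recon/reconstruction.obj \
    --reference case/ground_truth.obj --nipples case/anatomy.json --out qc/
Rscript inst/cli/mammoplan.R qc-suite --n 10 --seed 1 --out qc10/
```

Every run writes a `manifest.json` (configuration plus hash) sufficient to
reproduce its outputs exactly.

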