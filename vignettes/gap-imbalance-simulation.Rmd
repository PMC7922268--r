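---
title: "Methods: virtual measured-resection TKA and gap-imbalance simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual measured-resection TKA and gap-imbalance simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneegap)
```

## The procedure being simulated

Mechanically aligned (MA) total knee arthroplasty resects the distal femur
and the proximal tibia perpendicular to each bone's mechanical axis. With
the measured-resection (MR) technique, the rotation of the femoral
component — and hence the orientation of the posterior femoral cut — is set
from bony landmarks rather than ligament tension. `kneegap` reproduces this
procedure virtually on 3D surface models that include articular cartilage
(as MRI-derived models do):

1. **Axes.** The femoral mechanical axis joins the hip center and the
   intercondylar notch; the tibial mechanical axis joins the ankle center
   and the center of the proximal tibia. The hip–knee–ankle angle (HKA) is
   the signed angle between the two, measured on the coronal plane of an
   anatomical frame (below); varus is positive, and the 0° boundary is
   assigned to the valgus group.
2. **Posterior reference axes.** Four standard references for the posterior
   cut are built per knee: the surgical transepicondylar axis (TEA, medial
   epicondylar sulcus to lateral epicondylar prominence), Whiteside's line
   (WSL, deepest trochlear-groove point to the intercondylar notch — the
   cut reference is its in-plane perpendicular, the standard surgical
   reading), the posterior condylar axis with 3° of external rotation
   (PCA + 3°), and the flexion–extension axis (FEA, the line joining the
   centers of circles fitted to each condyle's posterior articular profile
   in the sagittal plane).
3. **Cuts.** The distal femoral and proximal tibial planes are
   perpendicular to the respective mechanical axes, 9 mm from the most
   distal condyle / most proximal plateau. Each posterior femoral plane is
   perpendicular to the distal plane, parallel to its reference axis, and
   9 mm from the most posterior condylar point measured along the plane
   normal.
4. **Gaps and imbalances.** Per compartment, the extension gap is the
   distal femoral plus tibial resected thickness and the flexion gap is the
   posterior femoral plus tibial thickness. Medio-lateral imbalance
   (MLI) = lateral − medial gap; flexion–extension imbalance
   (FEI) = extension − flexion gap. The balance predicate asks that both
   compartments' |FEI| fall within a threshold (1, 2, 3 mm by default).

Thickness is measured at the extreme point of each compartment (the maximal
resected thickness of that condyle), which makes "9 mm from the most distal
condyle" an exact identity for the depth-defining compartment and lets every
synthetic-knee thickness be checked against a closed form.

## The anatomical frame and sign conventions

All orientation logic lives in one frame per knee: origin at the
intercondylar notch, `z` along the femoral mechanical axis (proximal), `x`
the epicondylar direction orthogonalized against `z` (lateral), `y`
anterior. `y`'s sign is fixed by the trochlear-groove landmark, which is
anterior by definition, so the same code handles both sides. A triad with
x-lateral / y-anterior / z-proximal cannot be right-handed for both knees;
`kneegap` keeps the anatomical meaning of the axes fixed and lets the world
handedness flip for left knees. No construction relies on cross-product
handedness — every derived direction is re-oriented explicitly against a
frame axis — which is why mirrored left/right knees produce bit-identical
compartment outputs (a tested invariant).

Two sign decisions worth stating:

* **HKA** is measured on the coronal projection (the 3D-vs-projected choice
  is not standardized); positive means the distal tibia deviates laterally.
* **External rotation** of the posterior reference moves the lateral end of
  the axis posteriorly. Geometrically this brings the cut plane closer to
  the lateral posterior condyle and therefore resects *less* lateral and
  *more* postero-medial bone — the classic reason external rotation is used
  to balance the flexion gap. A consequence tested explicitly: on a
  perfectly symmetric knee, PCA + 3° necessarily produces a flexion MLI of
  −w·sin 3° (w = 44 mm between posterior extremes ⇒ −2.30 mm). A perfectly
  balanced symmetric result under "PCA" is only obtainable with the
  rotation knob set to 0 (`run_config(pca_rotation_deg = 0)`).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| resection depth | 9 | mm | the simulated implant's nominal bone cut |
| PCA external rotation | 3 | degrees | standard MR offset from the posterior condylar axis |
| balance thresholds | 1, 2, 3 | mm | common FEI acceptability references |
| cartilage per surface | 2 | mm | 4 mm per compartment when healthy (femoral + tibial) |
| circle-fit objective | Kåsa | — | closed-form algebraic least squares; exact on exact arcs |

The Kåsa fit is chosen because it is deterministic and exact when the
points lie on a circle; on low-noise arcs it agrees with geometric least
squares to well under the 0.05 mm the tests demand. The geometric objective
is kept in the test suite as an independent oracle, not in the package.

## The synthetic cohort: what it emulates and what it does not

Real MRI-derived models for this kind of study are not publicly available,
so the package ships a parametric generator whose defaults *are* the stated
study population: a varus group (HKA 8.2 ± 3.6°, truncated to 0.1–22.7°)
and a valgus group (HKA −3.9 ± 3.4°, truncated to −15.7–0°), sampled as
631 + 107 knees by default.

Condyles are analytic primitives — circular arcs (medio-laterally extruded)
for the distal and posterior femoral facets, gently domed spherical caps
for the tibial plateaus — so that every extreme point, axis direction and
resected thickness has a closed form recorded in the model's `truth` list.
Deformity is imposed by rotating the tibia (and ankle landmark) in the
coronal plane about the proximal tibia center; the femoral side contributes
zero deformity by default. Cartilage is an outward radial offset;
compartment wear shrinks it, medially in varus knees and laterally in
valgus knees.

Two generator choices deserve justification:

* **Distal-dominant femoral wear** (`wear_post_frac = 0.25`). Wear in
  coronal-plane OA concentrates on the extension-facing distal femoral and
  tibial surfaces; the posterior condylar cartilage is relatively
  preserved (the classic erosion pattern — e.g. distal lateral femoral
  erosion in valgus knees). Applying only a quarter of the femoral
  compartment wear to the posterior facet is what gives the worn
  compartment a smaller extension than flexion gap, and hence the expected
  sign structure of the flexion–extension imbalances (e.g. negative lateral
  FEI under FEA in valgus knees). With facet-uniform wear that structure
  provably cannot appear, because per-compartment FEI reduces to distal
  minus posterior femoral thickness.
* **Anatomical covariances are placeholders.** Radii, condylar twist
  (posterior offset asymmetry, default 2.3 mm ≈ 3° over a 44 mm condylar
  span), trochlear orientation, plateau asymmetry and slope are drawn from
  truncated normals with means/SDs chosen to be morphologically plausible;
  the real population's joint distribution of these quantities is not
  printed anywhere and was *not* fitted. Cohort-level magnitudes from the
  generator are therefore not comparable to the study's numbers; only
  directional/structural properties are (and only those are asserted).

A green test establishes: exact arithmetic of the imbalance functionals,
exact axis recovery and cut geometry on noise-free analytic knees,
agreement with closed-form thickness oracles within 0.02 mm at the default
mesh resolution, exact left/right mirror symmetry, and the qualitative
cohort sign structure. It does not establish clinical realism of the
magnitudes, soft-tissue behaviour (explicitly out of scope), or anything
about segmentation/landmarking error on real MRI models.

## Numerical choices

* Default mesh resolution (2° arc steps, 17 medio-lateral samples, 2 mm
  radial plateau steps) keeps the worst-case thickness discretization error
  below 0.02 mm; the default φ-grids contain the exact facet extremes (0°
  distal, 90° posterior), so depth identities hold to 1e-9 on noise-free
  knees.
* The distal and posterior facets are disjoint analytic patches; the seam
  region between them carries no metric (no extreme of any tested direction
  lies there) and is deliberately left unmeshed.
* Extremal queries break ties by first occurrence (deterministic); on
  noise-free extruded arcs this pins both condyles' extremes to the same
  medio-lateral offset, so the inter-extreme spacing equals the condylar
  separation exactly.
* Circle fits reject collinear input at a 1e-8 relative singular-value
  tolerance; frames reject epicondylar axes within 0.5° of the mechanical
  axis; a cut that misses a compartment yields thickness 0 with a warning,
  not an error.
* Welch's unequal-variance t-test is used wherever "two-sample t-test" is
  unspecified, and Tukey HSD as the unspecified post hoc, with a
  compact-letter display computed by maximal-clique search over the
  not-significantly-different graph (exact for the small number of
  methods). The ANOVA treats methods as independent groups even though they
  are measured on the same knees — matching how such comparisons are
  usually reported — and this is a known simplification.
* All randomness flows from explicit seeds; `generate_knee` and
  `generate_cohort` restore the caller's RNG state.

## Known limitations

* Soft-tissue laxity, ligament release, implant geometry (anterior/chamfer
  cuts, insert thickness) and saw-blade kerf are not modeled.
* Landmarks are inputs (exact for synthetic knees, user-supplied JSON for
  real meshes); automatic landmark detection is out of scope.
* The generator's population realism is distributional, not statistical-
  shape-model grade; see the placeholder note above.
* Only ASCII STL is read/written (a text-only, self-round-tripping format);
  compartment labels travel in a sibling CSV because STL has no attributes.
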