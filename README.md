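# tibtor

Three-dimensional tibial torsion measurement on CT-derived bone surface
meshes.

Tibial torsion -- the axial rotation of the distal tibia relative to the
proximal tibia about the bone's long axis -- matters for in-/out-toeing,
post-traumatic deformity and osteotomy planning, but the established CT
measurements are two-dimensional: axes drawn by hand on two axial
slices, with the distal axis hostage to the highly variable position of
the fibula.  `tibtor` implements a fully 3D measurement on segmented
surface meshes (tibia, distal femur, fibula), the two classic 2D
techniques for comparison, a synthetic bone phantom with analytic ground
truth for validation, and the agreement statistics used to compare
raters and methods.  Intended users are musculoskeletal imaging and
orthopaedic-research groups working with segmented lower-limb CT.

## The measurement

After aligning the leg to a reference frame (mechanical axis
knee-centre-to-ankle-centre mapped to +y, anterior reference in the y-z
plane, left legs mirrored so +x is lateral), torsion is

```
torsion = angle( proj_P(PTA), proj_P(DTA) )   about the anatomical axis,
```

where `P` is the plane perpendicular to the anatomical axis and, with
external rotation positive:

* **PTA** (proximal tibia axis): first principal component of the
  tibiofemoral contact areas -- the tibial-plateau points closest to the
  two condylar tip clusters, detected by 2-means clustering of the
  distal 25 mm of the femur;
* **DTA** (distal tibia axis): second principal component of the 10 mm
  metaphyseal surface band directly proximal of the distal tibia joint
  plane (total-least-squares plane through nine plafond landmarks),
  without (**3D-T**) or with (**3D-TF**) the corresponding fibular band;
* **anatomical axis**: total-least-squares line through the area
  centroids of six shaft cross-sections 40-140 mm below the tibial
  plateau plane (fitted to eight plateau landmarks).

The 2D comparison methods share a proximal posterior-cortex tangent one
slice (1 mm) above the fibular head; distally, **Jakob** connects circle
centres fitted to the tibial and fibular contours 1 mm above the ankle
joint surface, and **Goutallier** connects the centres of tangents to
the medial and lateral malleolar articular aspects 1 mm below it.

Agreement statistics follow the conventions of reliability studies:
ICC(A,1) (two-way random effects, absolute agreement, single measures)
for interobserver agreement and ICC(A,k) for inter-method agreement,
both with McGraw-Wong F-based confidence intervals, plus paired and
independent t-tests, Shapiro-Wilk normality checks and mean absolute
differences.

## Worked example

```r
library(tibtor)

# a synthetic right leg with 30 degrees of torsion and CT-scale vertex noise
ph  <- generate_phantom(phantom_spec(torsion = 30, noise_sd = 0.3, seed = 7))
res <- measure_torsion_all(ph$bones, seed = 1)
sapply(res, function(r) r$angle)
#>      3D-T      3D-TF      jakob goutallier
#>  28.66762  -59.23392   30.47118   31.46960
```

Three of the four methods recover the 30-degree construction truth to
within ~1.5 degrees at this noise level.  The 3D-TF value is not an
error: including the fibula reorders the principal components of the
distal slab, so the "second component" definition lands ~90 degrees away
-- its own construction ground truth here is `ph$ground_truth$torsion_3d_tf`
(-60), which it matches.  See the methods vignette
(`vignettes/torsion-methods.Rmd`) for why, and for the
`dta_component` switch.

```r
# interobserver agreement, two readers on five legs
icc_agreement_single(cbind(c(30.1, 24.6, 28.4, 35.2, 22.9),
                           c(29.5, 25.0, 28.9, 34.1, 23.6)))
#> ICC(A,1) = 0.988 (95% CI 0.887-0.999), n = 5 subjects, k = 2 raters
```

Real data enter through `read_mesh()` (STL binary/ASCII, PLY ASCII),
`read_landmarks()` (one JSON per leg: 9 plafond points, 8 plateau
points, knee/ankle centres, anterior reference, side) and
`read_rater_table()` (CSV).  A small command line lives in
`inst/cli/tibtor`:

```sh
tibtor phantom --torsion 30 --seed 7 --out phantom/
tibtor measure --tibia phantom/tibia.stl --femur phantom/femur.stl \
       --fibula phantom/fibula.stl --landmarks phantom/landmarks.json \
       --variant all --out result.json
tibtor stats --table readers.csv
```

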