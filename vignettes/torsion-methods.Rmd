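---
title: "Measuring tibial torsion on 3D bone models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring tibial torsion on 3D bone models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tibtor)
```

Tibial torsion is the axial rotation of the distal tibia relative to the
proximal tibia about the bone's long axis, reported in degrees with
external rotation positive.  Classic CT measurements pick two axial
slices and draw axes by hand; `tibtor` implements a fully
three-dimensional measurement on segmented bone surface meshes, the two
classic 2D techniques (Jakob; Goutallier) for comparison, a parametric
synthetic bone phantom with analytic ground truth, and the agreement
statistics (intraclass correlation, t-tests, mean absolute differences)
used to compare raters and methods.

## The measurement model

All computation happens in a patient-independent reference frame: the
mechanical axis of the tibia -- operationalised as the line from the
knee-joint centre to the ankle-joint centre, both given as landmarks --
is aligned with +y (proximal up), the ankle centre is placed at the
origin, and the leg is rotated about y until an anterior reference point
(patella centroid or tibial tuberosity) lies in the y-z plane with
z > 0.  Left legs are mirrored (x to -x) before alignment so that +x is
lateral on both sides and left/right values are directly comparable.
The mechanical axis has many published operationalisations; because
torsion is an angle *about* the long axis, it is quite insensitive to
small differences between them, and a two-landmark definition keeps the
tool independent of the femoral head, which is often outside the scanned
volume.  The `reference_frame` stored in every result records exactly
what was used.

**Proximal tibia axis (PTA).**  The distal 25 mm of the femur is
clustered into two condyles (k-means, k = 2, k-means++ initialisation,
best of 10 restarts).  Each condylar tip cluster is the condyle surface
within 1 mm of its most distal point; mapping every tip point to the
closest point on the tibial surface yields the tibiofemoral contact
areas, and the PTA is their first principal component.  This axis
represents the kinematically loaded part of the plateau rather than the
posterior cortical rim the 2D methods use.

**Distal tibia axis (DTA).**  A total-least-squares plane (the distal
tibia joint plane, DTJP) is fitted to nine manually selected points on
the tibial plafond.  The 10 mm of metaphyseal surface directly proximal
of that plane -- optionally including the corresponding fibular band --
forms the distal slab, and the DTA is the *second* principal component
of the slab (the variant including the fibula is called 3D-TF, the
tibia-only variant 3D-T).

**Anatomical axis and the torsion angle.**  A plane is fitted to eight
plateau points; the whole-bone first principal component, oriented
distally, gives the shaft direction; six cross-sections at 40-140 mm
(20 mm steps) below the plateau-plane centre are sliced, and the
anatomical axis is the total-least-squares line through their area
centroids.  Both PTA and DTA are projected onto the plane perpendicular
to the anatomical axis and the torsion angle is the signed angle from
the projected PTA to the projected DTA about the proximally-directed
anatomical axis (right-hand rule; with +x lateral this makes external
rotation of the distal segment positive).  Because both axes come from
principal components they are lines, not arrows: each carries a
180-degree direction ambiguity.  We resolve it toward the smaller
absolute angle, so reported torsion lies in (-90, 90] -- the same rule
the 2D methods use.  A fixed sign convention on eigenvectors (positive
dot product with +x, then +y, then +z) additionally makes every axis
reproducible run to run.

**2D reference methods.**  Both use the same proximal axis: a tangent
along the posterior cortex of the tibial head in the axial slice 1 mm
proximal to the fibular head apex.  Distally, the Jakob technique fits
one circle into the tibial and one into the fibular contour 1 mm
proximal to the ankle joint surface and connects the centres; the
Goutallier technique places tangents on the articular aspects of the
medial and lateral malleolus 1 mm below the joint surface and connects
the tangent centres.  The torsion angle is the axial-plane angle from
the proximal to the distal axis, external positive, in (-90, 90].

## Tunable constants

All pipeline constants live in `run_config()` and default to the
protocol values:

| constant | default | meaning |
|---|---|---|
| `condyle_band_mm` | 25 | distal femoral band for condyle detection |
| `tip_band_mm` | 1 | condylar tip band |
| `slab_thickness_mm` | 10 | distal metaphyseal slab |
| `slab_side` | `"proximal"` | side of the DTJP the slab is taken from |
| `dta_component` | 2 | principal component defining the DTA |
| `shaft_offsets_mm` | 40..140 | anatomical-axis section offsets |
| `slice_offset_mm` | 1.0 | 2D slice offset (one CT slice) |
| `n_samples` | 8000 | sample budget for the stochastic stages |

Two of these deserve comment.  The slab is taken *proximal* of the DTJP:
distal of the plafond there is almost no tibial bone, so the distal
reading of "extracted distal from the joint plane" is anatomically
implausible; the side remains switchable for sensitivity analyses.  The
DTA defaults to the second principal component.  On an isolated
elliptical metaphysis (transverse variances larger than the 10 mm
height) the first component is the mediolateral major axis and the
second the anteroposterior minor axis; once the fibula is included, the
between-bone separation adds variance along the inter-malleolar
direction and the component order can swap, placing the second component
roughly 90 degrees from the tibia-only one.  This is a property of the
definition, not a bug; the phantom's ground truth for 3D-TF is therefore
computed from the construction covariance rather than assumed equal to
the other methods, and `dta_component = 1` is available.  Runs where the
selected component's variance is within 5% of a neighbouring component's
set an `ambiguous` flag in the diagnostics.

## Numerical choices

*Surface integrals instead of surface sampling.*  PCA inputs (contact
areas, distal slab, whole-bone moments) are integrated exactly over the
triangulation: each triangle contributes its three edge midpoints with
weight area/3, a degree-2 quadrature whose weighted first and second
moments equal the continuous surface integrals.  Random area-uniform
sampling at a feasible budget would leave one-to-three degrees of
eigenvector noise in the distal-axis estimate (the transverse variance
gap is modest), which would dwarf the quantity being measured; with
exact moments the only stochastic stage left is the condyle clustering,
whose labels are stable for any seed once two condyles exist.  A seeded
area-uniform sampler (`sample_surface()`, and
`extract_distal_slab(method = "random")`) remains available.

*Clipping and slicing tolerances.*  Triangle-plane clipping treats
vertices within 1e-6 mm of the plane as inside, so geometry lying
exactly on a boundary (the flat plafond sits exactly on the slab plane)
cannot flip in and out under rounding.  Mesh-plane intersection computes
one intersection point per crossing edge and chains segments by edge
identity, so contours close exactly; vertices numerically on the plane
are nudged by 1e-9 mm.

*Robust 2D tangents.*  Manually placed tangents are emulated by a
Tukey-biweight iteratively reweighted total-least-squares line on the
posterior-facing part of the convex hull (proximal tangent) or on the
contour arc whose outward normals point toward the inter-malleolar
midpoint within 45 degrees (malleolar tangents).  The smooth weights
make the tangent a continuous function of the contour: segmentation
noise fades edges out gradually instead of flipping them in and out of a
hard inclusion set.  The tangent "centre" is the robust weighted
centroid on the fitted line.

*Circle fits* use a Pratt-style algebraic fit followed by one
Gauss-Newton refinement on geometric distance, so partial arcs are
handled without bias toward small radii.

*Meshes are cleaned on load* (duplicate vertices merged at 1e-6 mm,
zero-area faces dropped); STL stores every triangle with its own vertex
copies, and without merging each point would be weighted by its face
count in every moment computation.  Units are millimetres everywhere and
are never inferred from file headers.

## The synthetic phantom

`phantom_spec()` / `generate_phantom()` build a watertight tibia (lofted
elliptical cross-sections; a flat posterior facet on the tibial head; a
distal 10 mm elliptic band rotated to the requested azimuth; a flat
plafond; a separate medial malleolar block below the plafond), a distal
femur (two condylar spheroids whose tips sit over the plateau contact
points), and a fibula (cylinder with a proximal apex and a flat medial
facet at the lateral malleolus).  Landmarks are placed by rule (evenly
spaced on the plafond and plateau rims), so landmark noise can be
studied separately from surface noise.  Defaults reflect adult lower-leg
dimensions: 360 mm plateau-to-plafond length, 38 mm plateau half-width,
44 mm condylar spacing, 25 x 18 mm distal semi-axes, fibula of radius
8 mm at 40 mm offset.  Vertex noise is Gaussian and seeded; 0.3 mm
corresponds to the order of CT in-plane resolution (0.4 mm).

Every axis the pipeline estimates has an analytic counterpart computed
from the construction parameters -- closed forms for the condyle line,
the posterior facet and the malleolar centre line, and exact part-wise
surface moments for the distal-slab covariance -- so the phantom tests
*internal consistency*: that the implementation measures what its
definitions say.  It deliberately does not model cortical thickness,
anatomical shape variation, segmentation artefacts, or a talus (the
Goutallier slice level is approximated by the joint-plane level).
Passing phantom tests therefore demonstrates correctness of the
geometry, not clinical accuracy on real anatomy.

The test suite and the acceptance script run the whole family at desk
scale: seven phantoms with torsion -10 to 50 degrees, noise-free and at
0.3 mm vertex noise, at the default mesh density (~2.5 mm edges, ~6000
tibial vertices); recovery errors stay within 2 degrees noise-free and
3 degrees under noise for all four methods, rigid transforms and
mirroring change results by well under 0.1-0.2 degrees, and reruns with
different seeds agree to better than 0.5 degrees.

## Agreement statistics

`icc_agreement_single()` implements ICC(A,1) (two-way random effects,
absolute agreement, single measures) and `icc_agreement_average()`
ICC(A,k), both from the two-way ANOVA mean squares, with McGraw & Wong
F-based 95% confidence intervals (the average-measures bounds are the
single-measures bounds stepped up by the Spearman-Brown relation).  The
interval is reported as `NA` for degenerate tables where the
Satterthwaite degrees of freedom collapse.  Complete cases are required;
there is no imputation.  `paired_t()`, `independent_t()` (pooled by
default, Welch switchable), `normality_check()` (Shapiro-Wilk) and
`mean_abs_diff()` round out the toolkit, and
`method_comparison_report()` produces the pairwise inter-method table
(average-measures ICC, mean difference with SD and range, MAD,
normality of the differences, significance at p <= 0.05, two-sided
throughout).

## Worked example

```{r example, eval = FALSE}
ph <- generate_phantom(phantom_spec(torsion = 30, noise_sd = 0.3, seed = 7))
res <- measure_torsion_all(ph$bones, seed = 1)
sapply(res, function(r) r$angle)
#      3D-T      3D-TF      jakob goutallier
#  28.66762  -59.23392   30.47118   31.46960
ph$ground_truth$torsion_3d_tf
# [1] -60
```

(The 3D-TF value is the expected consequence of the component reordering
discussed above, and matches its own construction truth.)

## Known limitations

- The phantom is a geometric idealisation; no claim about agreement with
  manual measurements on patient CTs is made or tested.
- The Goutallier "talar surface" level is approximated by the distal
  joint-plane level because no talus mesh is in scope.
- Binary PLY is not read (ASCII PLY and both STL flavours are).
- The DTA component-order sensitivity means 3D-TF values are only
  comparable between runs using the same `dta_component` and slab
  definition; the result JSON records both.
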