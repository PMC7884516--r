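Package: tibtor
Title: Three-Dimensional Tibial Torsion Measurement from Bone Surface Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures tibial torsion on CT-derived, segmented bone surface
    meshes (tibia, distal femur, fibula) with a fully three-dimensional
    technique: the proximal tibia axis is the first principal component of
    the tibiofemoral contact areas, the distal tibia axis is a principal
    component of a 10 mm metaphyseal surface band above the distal joint
    plane (with or without the fibula), and the torsion angle is measured
    between both axes after projection onto the plane perpendicular to the
    anatomical shaft axis. Two established axial-slice reference methods
    (Jakob and Goutallier) are provided for comparison, together with a
    parametric synthetic bone phantom generator with analytic ground truth,
    agreement statistics (intraclass correlation with confidence intervals,
    paired and two-sample t-tests, Shapiro-Wilk normality check, mean
    absolute differences) and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
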