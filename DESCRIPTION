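Package: ventmesh
Title: Automatic Personalization of High-Order Ventricular Cardiac Meshes
Version: 0.1.0
Authors@R: person("ventmesh", "developers", role = c("aut", "cre"),
    email = "ventmesh@example.org")
Description: Fully automatic construction of tricubic Hermite finite-element
    meshes of the cardiac ventricles (left-ventricular or biventricular) from
    binary segmentation masks. The pipeline tailors a truncated-ellipsoid
    template to shape measurements extracted from the mask, registers the
    rasterized template to the mask with a multi-pass control-grid non-rigid
    registration under a level-of-detail schedule, projects the resulting
    displacement field onto the mesh degrees of freedom by variational L2
    minimization, and enhances element quality by transmural linearization.
    Includes Jacobian-ratio quality metrics, isosurface fitting-error metrics,
    a synthetic phantom generator with analytic ground truth, and EX/VTK mesh
    writers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
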