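Package: atriofiber
Title: Left-Atrial Wall Segmentation, Rule-Based Myofiber Generation and
    Monodomain Electrophysiology
Version: 0.1.0
Authors@R: person("Atriofiber", "Developers", role = c("aut", "cre"),
    email = "maintainers@atriofiber.dev")
Description: Automated construction of left-atrial computational models:
    statistics-based segmentation of the atrial wall from contrast-enhanced
    voxel images with mitral-valve and pulmonary-vein tagging, constrained
    level-set smoothing and isotropic resampling, Laplace-Dirichlet surface
    and transmural myofiber generation on triangular and tetrahedral finite
    element meshes, and monodomain electrophysiology with the
    Courtemanche-Ramirez-Nattel human atrial cell model including conduction
    velocity tuning and local activation time analysis.  Synthetic phantom
    generators (voxel phantoms, slabs, an idealized shell atrium with a
    simplified region atlas) provide self-contained inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
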