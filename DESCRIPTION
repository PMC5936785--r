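Package: ventriflow
Title: Desk-Scale Left-Ventricular Hemodynamics with Trabeculated and
    Smoothed Endocardial Geometries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates paired smoothed and trabeculated left-ventricle-like
    cavities with mitral-side and aortic-side flow-development tubes, meshes
    them with an isosurface-stuffing lattice mesher, and solves incompressible
    flow through them with a low-dissipation equal-order P1 finite-element
    scheme: explicit Runge-Kutta time integration with a choice of convective
    (CONV) or energy-momentum-angular-momentum conserving (EMAC) non-linear
    form, non-incremental fractional-step pressure projection, an
    eigenvalue-style time-step estimator, and an optional Darcy porous-layer
    surrogate for trabeculae. Post-processing quantifies the intra-ventricular
    pressure drop from Freedman-Diaconis histogram modes, wall-shear-stress
    distributions, and Q-criterion vortex surface areas, and drives the
    thickness-by-porosity sensitivity sweep that scores how well a porous
    layer on a smoothed cavity reproduces a trabeculated one.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
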