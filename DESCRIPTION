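Package: blendsim
Title: Quality-by-Design Scale-Up of Pharmaceutical Powder Blending with
    Discrete-Element Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for developing and scaling up pharmaceutical powder
    blending processes under a quality-by-design workflow.  Implements
    FMEA risk scoring with Pareto thresholding, Box-Behnken response
    surface modelling with ANOVA and constrained design-space mapping,
    Monte-Carlo conversion of design spaces into robust operating spaces,
    a soft-sphere discrete-element engine with Hertz-Mindlin (no-slip)
    and JKR cohesive contact against rotating triangle-mesh walls,
    virtual bulk tests (static and dynamic angle of repose, basic flow
    energy) with an iterative calibration loop, and blending-homogeneity
    analysis (per-bin drug content, content uniformity as percent RSD,
    Carr index, T-index series) across blender scales and shapes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
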