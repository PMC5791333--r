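Package: tamsim
Title: Hybrid Discrete-Continuum Simulation of Tumor Growth with
    Macrophage Subtypes and Vascular Remodeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a vascularized tumor lesion growing in a 2D capillary
    grid, coupled to discrete tumor-associated macrophage agents of the M1
    (cytotoxic), M2 (growth-promoting) and Tie2-expressing (TEM,
    vasculature-stabilizing) phenotypes. Tumor tissue advances by Darcy flow
    driven by oxygen-dependent net proliferation; oxygen, cytokines, tumor
    angiogenic factor and angiopoietin-2 are steady-state reaction-diffusion
    fields; the vessel network sprouts semi-stochastically up angiogenic
    gradients and adapts segment radii under pressure, with TEM contact
    shielding vessels from collapse. A case runner executes the eight
    macrophage-population scenarios and computes tumor radius, vascular
    surface area, subtype counts and vascular/tumor volume-ratio metrics.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    png
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
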