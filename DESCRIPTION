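Package: biofilmO2
Title: Patch-Scale Biofilm Oxygen Transport, Metabolism and Upscaling
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse phototrophic stream biofilms at the patch
    scale: digital elevation models and porosity from optical coherence
    tomography (OCT) intensity volumes, colour-based segmentation of
    biofilm patch types from macrophotographs, calibration and spatial
    analysis of O2 microsensor depth profiles, a coupled free-flow /
    Brinkman porous-media solver for steady two-dimensional flow and O2
    advection-diffusion-reaction, Nelder-Mead estimation of transport and
    metabolic parameters from measured O2 transects, and volume-weighted
    upscaling of patch metabolism to landscape-scale O2 budgets. A
    synthetic-data generator emulates the flume study design (patch
    geometry statistics, OCT-like volumes, macrophotographs, inlet
    velocimetry and forward-modelled O2 transects) so the whole pipeline
    is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, ImageAnalysis, Microbiome
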