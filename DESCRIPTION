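Package: poreNitrogen
Title: Porewater Nitrogen Zonation, Diffusive Fluxes, and Anammox Niche Metrics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for depth-resolved porewater nitrogen analysis in marine
    sediments. Reads and validates porewater solute profiles (nitrate, nitrite,
    ammonium, oxygen) with detection-limit censoring, derives the geochemical
    zonation of a core (oxic zone, nitrate depletion depth, nitrite accumulation
    interval, nitrate-ammonium transition zone, net nitrite consumption zones),
    computes Fick's-law diffusive boundary fluxes with tortuosity-corrected
    sediment diffusivities and cross-site nitrite/nitrate flux-ratio statistics,
    converts 16S gene copies and amplicon relative abundances into absolute
    microbial abundances with anammox niche-partitioning metrics, and
    forward-generates solute profiles from one-dimensional steady-state
    reaction-diffusion scenarios with analytic flux truths so every pipeline
    stage can be verified against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
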