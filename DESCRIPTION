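Package: wmhpenumbra
Title: Synthetic Multimodal MRI Analysis of White Matter Hyperintensity Penumbra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis chain for probing white matter
    hyperintensity (WMH) lesions and perilesional normal-appearing white
    matter (NAWM) with quantitative MRI. Generates synthetic brain phantoms
    (tissue labels, multi-echo spin-echo and diffusion-weighted signals with
    Rician noise), fits myelin water fraction and intra/extracellular
    geometric mean T2 maps by extended-phase-graph-corrected regularized
    non-negative least squares, fits the diffusion tensor for FA and MD maps,
    builds 2 mm perilesional distance rings with CSF and stroke exclusions,
    and fits the distance-by-group, distance-by-hemisphere and lesion-volume
    linear mixed-effects models with Tukey-adjusted post hoc contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse
Config/testthat/edition: 3
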