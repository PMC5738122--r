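Package: resumeqmri
Title: Quantitative MRI Relaxometry from a Dual Spoiled Gradient-Echo Protocol
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analytic reconstruction of voxelwise R1, R2* and proton-density
    maps from one single-echo and one double-repetition-time multi-echo
    spoiled gradient-echo acquisition, as used to extend a clinical
    susceptibility-weighted imaging scan into a full quantitative MRI
    protocol. Includes the closed-form two-branch variable-flip-angle R1
    solution with an explicit branch-selection rule, weighted-least-squares
    R2* fitting with per-echo bandwidth weights, a delta-method noise model
    with optimal flip-angle search, a multispectral non-local-means denoiser
    with spatially varying noise maps and adaptive search balls, a
    forward-model digital phantom generator, reproducibility/accuracy
    assessment utilities, minimal NIfTI-1 input/output and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
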