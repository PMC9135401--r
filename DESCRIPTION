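Package: blastemaST
Title: Spatial Transcriptomics Analysis of the Regenerating Digit Blastema
Version: 0.1.0
Authors@R:
    person("Regeneration", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for spot-level spatial transcriptomics
    of the regenerating digit tip: region-versus-rest Wilcoxon differential
    expression with expressing-fraction specificity ratios, three-criterion
    blastema gene-signature selection with reductive minimization,
    expression-binned control module scoring (pathway, metabolic and
    cell-cycle programs with S/G2M/G1 phase assignment), and the SpatialTime
    proximal-distal gradient statistic (minimum distance of each spot to a
    reference polyline drawn along the residual bone stump, min-max scaled per
    sample). Ships a Visium-like synthetic data generator with planted ground
    truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
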