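Package: fundusroi
Title: Landmark-Anchored Region-of-Interest Classification of Widefield Fundus Images
Version: 0.1.0
Authors@R:
    person("fundusroi", "developers", email = "fundusroi@example.org", role = c("aut", "cre"))
Description: Tools for multi-label ocular disease classification on
    ultra-widefield fundus images using disease-specific regions of
    interest. Locates the optic disc and macula, extracts square crops
    whose edge length is a multiple of the optic-disc box diagonal,
    routes disease labels to three classifier branches (optic-disc,
    macula, whole image), tunes per-disease decision thresholds by
    maximizing sensitivity times specificity, and reports one-vs-rest
    and micro-average metrics with repeated-run confidence intervals.
    Includes a synthetic fundus-scene generator so the entire pipeline
    is testable without clinical data, plus ablation harnesses for ROI
    size and backbone choice.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
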