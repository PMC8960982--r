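Package: repconn
Title: Model-Free and Model-Based Representational Connectivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for representational connectivity analysis (RCA) between
    brain regions of interest, based on representational dissimilarity
    matrices (RDMs). Implements model-free RCA (direct correlation of two
    regions' neural RDMs), 1-model RCA (correlation of the two regions'
    time courses of fit to a common model RDM) and 2-model RCA (lagged
    correlation of fits to region-specific model RDMs), together with a
    synthetic two-region pattern simulator (static, time-resolved with
    common-input injection, and time-windowed information with congruent
    or incongruent delays), factorial model-RDM construction, and
    nonparametric group inference via exact one-sided Wilcoxon
    signed-rank tests. Three packaged simulation experiments demonstrate
    when model-free and model-based RCA disagree: intermediate models can
    produce spurious model-based connectivity, common input produces
    spurious model-free and 1-model connectivity, and 2-model RCA can
    detect transformed information when its temporal dynamics are
    congruent across regions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
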