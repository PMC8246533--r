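Package: bwsmaxdiff
Title: Best-Worst Scaling (MaxDiff) Experiments: Design, Scores and Choice Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for object-case best-worst scaling (maxdiff) choice
    experiments: construction and diagnostics of nearly balanced incomplete
    block designs for choice cards, counting-based best-worst scores on a
    standardized ratio scale, the maxdiff pair-choice likelihood with pooled
    conditional-logit, mixed-logit (maximum simulated likelihood with Halton
    draws) and latent-class (EM) estimators, AIC/BIC/CAIC class selection,
    share-of-preference summaries, posterior class profiling, and a synthetic
    respondent generator for end-to-end testing. Motivated by a best-worst
    study of intrahousehold milk-allocation decisions under a milk price
    increase among low-income households in peri-urban Nairobi.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
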