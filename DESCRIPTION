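Package: tteclaims
Title: Target Trial Emulation of Gout-Flare Prophylaxis Strategies from
    Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Emulates two target trials of colchicine for cardiovascular and
    limb risk reduction in patients with peripheral artery disease and gout,
    using claims-style data. Trial 1 compares colchicine with NSAID initiators
    at urate-lowering-therapy start using stabilized inverse-probability-of-
    treatment weights and weighted Kaplan-Meier risk curves; Trial 2 compares
    long-term with short-term (90-day) colchicine strategies using a
    clone-censor-weight estimator with time-varying censoring weights and a
    weighted pooled logistic outcome model. A seeded synthetic claims
    generator with a Monte-Carlo counterfactual oracle makes every stage of
    the pipeline verifiable without access to the original Medicare data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    survival,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
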