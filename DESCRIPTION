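Package: domex
Title: Detecting Discontinuous Protein Domains by Segment Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extends continuous-domain boundary predictors to the detection of
    discontinuous protein domains. Non-adjacent sequence segments of a query
    chain are concatenated into putative domains and searched against a
    single-domain sequence library; assemblies are accepted through a
    template-similarity score, a symmetry index on the per-segment alignment
    statistics, a relative length-error filter, and a profile-profile
    alignment score with predicted secondary structure. Includes sample
    construction, recall/precision/MCC and domain-overlap (NDO) evaluation,
    threshold calibration by exhaustive grid search, and a deterministic
    synthetic-fixture generator so the whole pipeline runs without external
    databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
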