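Package: crossage
Title: Age-Associated Transcript Selection and Directed Association Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-organ aging transcriptome analysis: covariate
    harmonization (z-scoring and empirical-Bayes batch adjustment applied to
    consecutively fitted subgroups) with the correction order chosen by
    principal variance component analysis (PVCA); iterated shadow-feature
    random-forest (Boruta-style) selection of age-associated transcripts in
    numeric- and categorical-age modes; unsigned weighted co-expression
    modules with eigengenes and antiparallel subgroup splitting; and an
    all-versus-all feature-selection network ("CrossBoruta") with the
    asymmetric association strength (AAS) statistic, hub scores and
    closeness centrality. A synthetic cohort generator emulating a
    7-organ x 2-strain x 2-sex x 5-age factorial design provides ground
    truth for parameter-recovery testing of every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ranger,
    lme4,
    sva,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
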