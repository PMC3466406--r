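Package: lihnet
Title: Logical Interaction Hypergraph Analysis of Signaling Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Qualitative modeling of signal transduction networks as logical
    interaction hypergraphs with multivalued logic, incomplete-truth-table
    gates and reaction time scales. Computes partial logical steady states
    under input and perturbation clamps, enumerates support-minimal
    intervention sets, derives the signed interaction graph and its
    elementary feedback loops, scores model predictions against discretized
    observation sets, performs structural sensitivity analysis and variant
    enumeration, extracts canalizing-input hierarchies via exact prime
    implicant covers, and provides the statistical layer used to discretize
    replicate fluorescence assays (mixed linear model with many-to-one
    contrasts) and to test intervention-target overlap with mutation
    databases (one-tailed Fisher exact test). Ships reduced hepatocyte
    mitogen cross-talk fixtures and seeded synthetic generators for models
    and assay data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    multcomp,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
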