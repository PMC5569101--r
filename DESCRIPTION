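Package: signcon
Title: Sign-Consistency Analysis of Expression Profiles on Signed Regulatory Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Confronts gene-expression profiles with a signed, directed
    regulatory graph by global sign-consistency reasoning. Provides
    three-sign discretization of expression matrices with holdout-based
    threshold selection, shortest-path subgraph extraction and
    degree-one compaction of influence graphs, exact consistency
    checking with minimal-correction (MCOS) and sign-switch (SCENFIT)
    repairs, seven-class sign projection over the union of consistent
    colorings, frequency-score signatures with Fisher ranking between
    two profile classes, in-silico single-node perturbation scoring
    (top perturbation scores), and a synthetic-data generator producing
    signed graphs, planted-consistent labelings and two-class
    expression matrices for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
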