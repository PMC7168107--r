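Package: physdx
Title: Model-Based Diagnosis and Troubleshooting of Neuromuscular Complaints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Consistency-based diagnosis over a typed anatomical influence
    graph (nerve roots, nerves, muscles and dermatomes) under a weak fault
    model. Failed clinical tests are turned into conflict sets by ancestor
    closure, subset-minimal diagnoses are enumerated as minimal hitting sets
    with normalized probabilities, and an information-gain-driven probing
    loop recommends the next test to discriminate between candidate
    diagnoses. Includes a seeded fault-injection scenario simulator, the
    associated evaluation metrics (diagnosis-set size, weighted false
    positive rate, health-state ROC AUC, top-K containment, wasted effort),
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
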