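Package: triagetree
Title: Authoring, Validation and Deterministic Execution of Clinical
    Decision-Tree Algorithms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, statically validating, serializing and
    deterministically executing Boolean decision-tree clinical algorithms of
    the kind used for pediatric triage at primary-care level. Provides a
    three-valued (Kleene) condition engine with staged questioning, emergency
    interrupts, severity-first diagnosis proposal with explanation traces and
    accept/refuse review; weight- and age-band posology computation and
    whole-table verification; likelihood-ratio and post-test-probability
    algebra for branch design including comorbidity-adjusted cutoff
    selection; a synthetic demo algorithm and labelled patient-case
    generator; and a QA harness with static lint, batch corpus execution,
    expectation checks and automated non-regression diffing between
    algorithm versions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
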