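Package: adra
Title: Autonomous Data-Driven Research Agent Framework
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Provider-agnostic framework for autonomous data-driven research
    on structured biomedical tables. Profiles a dataset, raises and reviews
    research questions with a text-generation provider, plans and generates
    analysis code, configures execution environments with an
    installation-tree backtracking algorithm, executes and adjudicates
    results on four dimensions, repairs failing code in bounded debug
    rounds, validates positive findings against a literature corpus and
    sibling datasets, deepens questions across evolution rounds, and scores
    the whole process with confusion-matrix, bootstrap and efficiency
    metrics. All provider-dependent steps run deterministically against
    recorded transcripts, so the complete loop is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
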