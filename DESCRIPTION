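Package: dmcurate
Title: Curation of Text-Mined Disease Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Turns raw text-mining output (molecular entities with subcellular
    localization plus sentence-level interaction evidence) into an
    expert-reviewable disease map. Interaction verbs are categorized against a
    replaceable lexicon, sentence-level evidence is aggregated into directed
    edges classed as activating, inhibiting, neutral, undefined, or incoherent
    and weighted by the number of distinct supporting publications, and
    entities are laid out in compartmental cellular bands. Provides edge
    filtering, cumulative publication-year timeline snapshots, a per-edge
    review workflow with an audit trail, and lossless export to viewer-ready
    graph JSON, SBGN-ML activity-flow documents, and review CSV tables. A
    seeded synthetic-corpus generator makes the whole pipeline testable
    without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
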