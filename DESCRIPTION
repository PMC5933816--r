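Package: ltrforest
Title: Identification and Superfamily Classification of LTR Retrotransposons
    with Relational Random Forests
Version: 0.1.0
Authors@R: person("ltrforest", "maintainers", email = "maintainers@ltrforest.org",
    role = c("aut", "cre"))
Description: A three-step pipeline that extracts candidate LTR-retrotransposon
    regions from a genome with a sliding window, delimits them by their
    conserved protein-domain hits (with merge, strand-split and trim rules),
    and classifies them into the Copia, Gypsy and Bel-Pao superfamilies with
    a relational random forest whose node tests are first-order queries over
    the domain-hit structure (occurrence, occurrence with a length bound,
    domain precedence, and occurrence counts of general domains). Includes
    the key-domain baseline, precision-recall evaluation under an
    overlap/containment true-positive rule, combined multi-class predictions
    with a None category, and a synthetic-data generator so the whole
    pipeline is testable without external genomes or domain databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
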