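Package: sdrftab
Title: Proteomics Sample Metadata in SDRF and IDF Tabular Formats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for the tabular sample-metadata representation used by
    proteomics repositories: parse, write, merge and split SDRF
    (Sample and Data Relationship Format) tables, parse and build IDF
    (Investigation Description Format) study descriptions, validate tables
    against structural rules, experiment-type templates and offline
    controlled-vocabulary snapshots, generate complete experimental designs
    (label-free, TMT, SILAC, fractionated, multiplexed), and derive
    downstream analysis inputs (search-parameter documents and flat
    annotation tables). Includes a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
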