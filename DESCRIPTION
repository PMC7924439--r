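Package: taxograph
Title: Linking Biodiversity Databases by Joining Taxon Identifier Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconciling taxon records across biodiversity
    databases by comparing graphs of external identifiers rather than
    taxonomic name strings. Streams taxon items out of Wikidata JSON entity
    dumps, reads the Open Tree of Life reference taxonomy and the GloBI
    taxon-graph archive into flat identifier lookup tables, links resources
    with an equi-join on shared external identifiers (NCBI, ITIS, GBIF, EOL,
    Index Fungorum, FishBase, WoRMS), and audits the linked graphs for
    overlap, per-scheme coverage, and same-scheme identifier conflicts.
    Includes a synthetic taxon-graph generator with planted ground truth for
    validating the linker and the audit metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
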