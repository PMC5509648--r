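Package: haystack
Title: Case-Control Discovery of Position-Specific Gapped Motifs in
    B-Cell Receptor Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mines annotated immunoglobulin heavy-chain (IgG-VH) amino-acid
    repertoires for disease-only motifs (DOMs): position-specific gapped
    motifs, anchored to the CDR3 start, that match a large fraction of
    case subjects and no control subjects. Implements the Haystack
    Heuristic, a breadth-first local search over a network of motifs
    connected by single-residue subsequence extensions and gap-adding
    cardinality extensions, with recursive restriction to temporary
    sub-repertoires and motif merging; the closed-form homogeneous-motif
    significance bound ML and its multiple-testing expected-count bound
    Mev; an in-memory indexed repertoire store for AIRR-style
    rearrangement tables; and a seeded synthetic repertoire generator
    with planted motifs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
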