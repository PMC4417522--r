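Package: taxmeon
Title: Taxonomic Concept Graphs for Species Checklists
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Represents species checklists as graphs of taxonomic concepts
    following the TaxMeOn meta-ontology. Assembles complete scientific names
    with authorship by traversing the checklist hierarchy, mints HTTP URIs and
    parses Life Science Identifiers (LSIDs), maps taxonomic concepts within
    and across checklists with a congruent/part-of/overlap relation algebra,
    detects and reifies nomenclatural and taxonomic change (genus transfers,
    lumps, splits) across checklist versions, and round-trips the whole model
    through RDF Turtle. Readers are provided for a checklist CSV dialect and
    Darwin Core Archive taxon cores; a synthetic checklist and revision
    generator supports parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'validate.R'
    'names.R'
    'identifiers.R'
    'mapping.R'
    'changes.R'
    'io-csv.R'
    'io-dwca.R'
    'turtle-write.R'
    'turtle-read.R'
    'fixtures.R'
    'examples.R'
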