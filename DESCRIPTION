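Package: mtgrouper
Title: Haplogroup Nomenclature Parsing and Phylogenetic Grouping of Human mtDNA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for working with human mitochondrial DNA haplogroup labels
    and for building phylogenetically informed secondary groupings of mtDNA
    samples. Parses haplogroup names under the cladistic notation and flags
    naming irregularities; computes nomenclature-based groupings (single
    character, single character plus L-digit, custom prefix maps) and
    most-recent-common-ancestor lookups in a haplogroup hierarchy; partitions
    rooted phylogenies into maximal clades under a pairwise path-distance
    threshold and assigns hierarchical dotted cluster addresses across a
    decreasing threshold ladder, with macro-, meso- and micro-haplogroup
    naming by clade MRCA; masks alignment positions, computes pairwise
    sequence distances, and compares grouping schemes through frequency
    tables, correspondence analysis, classical multidimensional scaling and
    within-group distance summaries. Includes seeded simulators for trees,
    haplogroup labels, population assignments and alignments, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
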