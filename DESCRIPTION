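Package: taxcomp
Title: Comparison of Species-Level Taxonomies with Congruence and
    Resolving-Power Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to compare alternative species delimitations of one set
    of specimens or terminal lineage units.  Implements the taxonomic index
    of congruence (Ctax), a Jaccard-type index on sets of speciation-event
    hypotheses, and the relative taxonomic resolving power index (Rtax),
    computed either on a rooted guide tree (species as clades, events as
    internal nodes) or tree-free from species counts via the common
    refinement of partitions.  Also provides pair-counting Rand and
    adjusted Rand baselines, haploweb-style species delimitation from
    phased diploid haplotypes (single-locus fields for recombination and a
    multi-locus majority consensus), seeded generators of guide trees,
    nested taxonomies and species-structured haplotype tables for
    property testing, and a packaged worked example on Malagasy
    Madascincus skinks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
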