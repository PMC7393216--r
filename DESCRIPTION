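Package: sodamag
Title: Abundance Profiling, Co-Occurrence Networks and Bioenergetics for
    Soda-Saline Lake Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis layer for shotgun-metagenome outputs
    from hypersaline alkaline (soda-saline) lake microbiomes.  Implements
    length-normalised gene-catalog abundance profiling with lowest common
    ancestor (LCA) taxonomy assignment and mOTU aggregation, coverage-based
    abundance of metagenome-assembled genomes (MAGs) with abundant-taxon
    detection, thresholded Pearson co-occurrence networks with module
    extraction, a declarative marker-gene rule engine for metabolic
    potential (including dissimilatory sulfite reductase directionality and
    glucan catabolic route typing), pH-corrected Gibbs free energies of
    sulfur redox reactions, and substrate-level ATP bookkeeping for glucan
    degradation routes.  A seeded synthetic-community generator with full
    ground truth exercises every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    stats,
    tibble,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
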