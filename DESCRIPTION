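Package: centrosat
Title: Satellite Array Annotation and Chromatin Profiling for Mouse
    Centromeres in Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Characterizes mouse centromeric and pericentromeric satellite
    DNA (minor satellite, major satellite, TLC satellite, telomeric repeat)
    in long sequencing reads: seed-and-extend discovery of satellite blocks,
    segmentation of reads into continuous (Type 1) and interspersed (Type 2)
    arrays, consensus-anchored monomer decomposition with per-position
    variation profiles, CENP-B box detection and intact/variant
    classification, neighbor-joining phylogenies of monomers under
    Jukes-Cantor distances, and input-normalized ChIP enrichment, nucleosome
    phasing and particle spacing on array references. A seeded synthetic
    data generator produces long reads and ChIP/input fragment sets with
    known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
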