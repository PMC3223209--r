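Package: coibarcode
Title: COI Barcode Libraries, Divergence Analysis and Specimen
    Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds cytochrome c oxidase subunit I (COI) barcode reference
    libraries from identified adult specimens, computes Kimura
    two-parameter (K2P) and p-distances with pairwise deletion,
    constructs neighbour-joining trees, partitions each species into
    barcode clusters at a divergence threshold to flag putative cryptic
    species with interim names, summarises divergence by taxonomic rank,
    and identifies unknown specimens (for example caterpillars) by
    nearest-neighbour matching against the library.  A Kimura (1980)
    substitution-model simulator generates reference libraries and query
    sets with recorded ground truth so every stage of the analysis can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
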