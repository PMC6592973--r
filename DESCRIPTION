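Package: apohybrids
Title: Parentage Inference for Apogamous Fern Species Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers the reticulate origins of hybrid taxa in species
    complexes that mix sexual and apogamous (apomictic) ferns. Provides
    clade-support-based typing of plastid haplotypes and nuclear alleles
    from gene trees, classification of reproductive mode from spore counts
    and ploidy from chromosome counts, a gamete-ploidy model covering the
    four canonical hybridization patterns and the hybridization-cycle
    mechanism of triploid apomicts, enumeration and ranking of hybrid
    parentage hypotheses under maternal plastid inheritance and allele
    constitution constraints, assembly and export of the resulting
    reticulogram, and a synthetic-data generator for end-to-end testing
    and parameter-recovery experiments. Ships a worked specimen table for
    the Diplazium hachijoense complex.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    igraph,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
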