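Package: mutseek
Title: Mapping EMS-Induced Mutations by Bulked-Segregant SNP-Index Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for forward-genetic identification of
    EMS-induced recessive mutations in plants from pooled resequencing data.
    Covers Mendelian segregation tests and F3 progeny-test genotype
    inference, modified-MutMap bulked-segregant mapping (per-site SNP
    indices, five-SNP sliding windows, candidate-region calling),
    strand-aware variant-effect annotation with a non-synonymous filter
    cascade and a natural-panel uniqueness screen, dCAPS/CAPS marker design
    with in-silico restriction digestion, F2 linkage mapping with the
    Kosambi function and LOD grouping, neighbor-joining protein phylogenies
    with bootstrap support, and relative expression quantification by the
    2^-ddCt method. A synthetic-data module generates genomes, gene models,
    mutation sets, pooled allele depths, marker and panel genotypes, protein
    families and qPCR Ct tables with the statistical structure of a
    recessive bulked-segregant study, so the whole chain is testable
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    graphics,
    grDevices,
    methods,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    phangorn,
    withr
Config/testthat/edition: 3
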