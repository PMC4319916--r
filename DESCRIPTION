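Package: scdmap
Title: Mapping Recessive Lethal Disease Variants in Small Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for mapping highly penetrant autosomal
    recessive disorders in small outbred families, built around the strategy
    used to identify the canine HES7 frameshift underlying spondylocostal
    dysostosis: underpowered family GWAS rescued by top-K chromosomal
    enrichment, candidate-region variant filtering through synteny and
    model-organism phenotype annotation, frameshift consequence prediction
    with HGVS naming and the 50-nt nonsense-mediated-decay rule, in-silico
    PCR-RFLP assay design and band-pattern genotype calling, and pedigree
    segregation plus allelic chi-squared case-control association. Includes
    a synthetic-cohort simulator (pedigrees, LD-structured SNP genotypes,
    candidate-region variant tables, gene models, synteny blocks and
    phenotype annotations) with a truth record for parameter-recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
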