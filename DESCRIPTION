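Package: autozygmap
Title: Autozygosity Mapping and Recessive-Variant Prioritization in
    Consanguineous Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects runs of homozygosity from dense genotype panels,
    derives loss-of-heterozygosity segments shared by affected siblings
    and absent from unaffected ones, and runs a recessive-model rare
    variant filter cascade with a per-variant audit trail, as used to map
    recessive disease genes in consanguineous nuclear families. Includes
    a gene-dropping pedigree simulator with known ground truth (planted
    autozygous segments and causal variant), windowed heterozygosity
    along chromosome arms, Wright path-counting inbreeding coefficients,
    Hardy-Weinberg genotype frequencies, carrier-screen summaries,
    per-residue protein variant-burden tracks, and the small bench-side
    quantifications (delta-delta-Ct, fluorescence ratios, colitis
    disease-activity and histology scores) that accompany such studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    Biostrings,
    vcfR,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
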