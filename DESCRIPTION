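Package: hlakit
Title: Computable IMGT/HLA Alignments, Allele Nomenclature Translation and
    Global HLA Frequency Maps
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Makes the text resources of the IPD-IMGT/HLA Database locally
    computable: parses the block-formatted IMGT alignment dialect into
    positional allele-by-position tables, reads the allele-list history,
    builds per-locus gene-feature atlases (including the non-standard
    hybrid/join/novel/segment feature nomenclature of pseudogenes and gene
    fragments) and a gene gazetteer, validates and translates allele names,
    GL Strings, GL String Codes and whole genotype datasets across database
    release versions, answers positional and amino-acid-motif queries over
    alignments, and renders global frequency heatmaps for alleles, motifs
    and multi-locus haplotypes from population frequency tables by
    inverse-distance-weighted gridding. Includes seeded synthetic-data
    generators emulating every input dialect so the full pipeline is
    testable offline.
License: GPL (>= 3)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
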