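Package: flanklift
Title: Cross-Assembly SNP Reconciliation by Flank-Sequence Remapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies SNPs whose coordinates, alleles, and genotypes are
    consistently recoverable across two versions of a reference genome.
    Flanking sequences around each SNP are remapped by exact full-length
    matching on both strands, confirmed reciprocally between assemblies,
    and filtered by panel-wide genotype concordance; the resulting reliable
    set drives coordinate liftover and merging of variant callsets produced
    against different reference versions. Includes a paired-assembly
    simulator with a ground-truth coordinate map so every stage can be
    validated without external data, and flank-composition diagnostics
    (trinucleotide frequencies, GC content, Welch t-tests) that
    characterise discordance-prone sequence context.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    vcfR,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
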