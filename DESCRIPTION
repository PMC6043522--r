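Package: yeastpopgen
Title: Population Genomics of Yeast Domestication from Pileup Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable implementations of the computational procedures used in
    population-genomic surveys of wild and domesticated Saccharomyces
    cerevisiae: allele-fraction genotype calling from site pileups with
    per-isolate heterozygosity profiling, repeated random haplotype sampling
    (RRHS) consensus phylogenetics, nucleotide diversity and polymorphism
    partitioning between ecological groups, flow-cytometry-adjusted aneuploidy
    and gene copy-number calling from 1000-bp coverage frames, and windowed
    introgression/HGT scanning against a multi-species reference library.
    A synthetic diploid-cohort generator with full ground truth makes every
    stage testable end to end without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn
Config/testthat/edition: 3
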