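Package: poolkdr
Title: Pool-Seq Allele-Frequency Contrast Scans for Insecticide-Resistance Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for contrasting pooled-sequencing allele frequencies between
    insecticide-exposure phenotype groups (knockdown-resistant, recovered, dead)
    of Aedes aegypti or similar designs. Implements the full genome-scan
    pipeline from per-library nucleotide count tables: depth, base-quality and
    repetitive-region site filters; polymorphic-site detection against a
    reference assembly; a replicate-concordance goodness-of-fit screen; a
    per-site heterogeneity chi-square with LOD transform and expected
    heterozygosity; per-chromosome Benjamini-Hochberg significance calling;
    codon-aware variant effect annotation against FASTA/GFF3 gene models;
    resistance-category summaries with one-way ANOVA of LOD scores; selection
    direction and frequency-bin classification; and an individual-genotype
    contingency analysis (chi-square, Pearson residuals, allele frequencies).
    A synthetic-data generator produces reference genomes, gene models, pooled
    counts with two-stage (pool + read) sampling, and genotype tables so that
    every stage is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
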