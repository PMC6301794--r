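Package: macrospace
Title: Nutrient-Space Phenotyping and Phenotype-Based Introgression
    Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for mapping natural variation in dietary
    sugar tolerance between closely related Drosophila species.
    Implements nutrient-space phenotype statistics over a yeast-by-sucrose
    diet grid (pupariation index, survival and development-time metrics,
    diet calorie model, Pearson correlations against diet axes, omega
    squared ANOVA effect sizes, genotype difference surfaces); a forward
    simulator of phenotype-based backcross introgression with female-only
    recombination, diet selection at tolerance loci, and pooled-sequencing
    readout; introgression-region mapping from species-diagnostic SNP
    frequencies in genomic windows; sequence-divergence analytics
    (sliding-window SNP density with background correction, Nei-Gojobori
    substitution classification, Ka/Ks with Jukes-Cantor correction,
    substitution-class contingency tests); and gene-set overlap statistics.
    A synthetic-data module generates every input the pipeline consumes so
    the full analysis is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
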