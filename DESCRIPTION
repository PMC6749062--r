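Package: lohqtl
Title: Simulating Loss of Heterozygosity, Inbreeding and QTL Mapping in Hybrid Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how genomic heterozygosity erodes in hybrid diploid
    yeast and how the resulting homozygous allele combinations map to
    quantitative traits. The package simulates phased heterozygous-SNP maps
    with realistic block structure, meiosis at chromatid resolution (tetrads
    with strict 2:2 segregation), intra- and inter-tetrad mating designs,
    targeted uniparental disomy with its marker/tetrad-viability screen,
    serial-transfer co-culture competitions read out as marked-cell fractions,
    and a from-scratch single-QTL genome scan (Haley-Knott regression LOD)
    with permutation-based genome-wide thresholds, inheritance-mode
    classification and percent-variance-explained estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
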