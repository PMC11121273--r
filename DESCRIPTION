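Package: popconserve
Title: Genetic Diversity, Inbreeding and Family Structure for Small
    Conservation Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-genotyping analysis toolkit for small livestock
    conservation populations genotyped at genome-wide SNPs (e.g. by
    genotyping-by-sequencing). Provides a genotype-matrix data model with
    VCF and PLINK PED/MAP text readers and writers, SNP and sample quality
    control with a per-criterion report, per-locus and population genetic
    diversity statistics (minor allele frequency, observed and expected
    heterozygosity, polymorphism information content, effective allele
    number, proportion of polymorphic markers, LD-based effective
    population size), PLINK-style detection of runs of homozygosity and
    the ROH-based genomic inbreeding coefficient F_ROH, VanRaden genomic
    relationship and identity-by-state distance matrices, principal
    component analysis, neighbor-joining dendrograms, threshold-based
    sire-family partitioning, and a pedigree-structured genotype simulator
    with planted autozygous tracts for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
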