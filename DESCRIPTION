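Package: poolqtl
Title: Pooled-DNA Allele-Frequency GWAS and Multi-Environment QTL Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mapping quantitative trait loci from pooled-DNA
    allele-frequency genotypes in multi-environment accession panels.
    Implements thermal-time (growing-degree-day) flowering phenotypes,
    allele-frequency SNP quality filters, a VanRaden genomic relationship
    matrix, an EMMA-style REML kinship mixed model with Wald tests and a
    Bonferroni threshold on the Li-Ji effective number of independent
    markers, forward-selection MultiQTL models with collinearity
    clustering, cross-location QTL consolidation, candidate-gene joins and
    short-motif search on fragmented assemblies, plus a seeded synthetic
    panel generator with planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
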