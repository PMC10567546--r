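Package: rvpqtl
Title: Rare-Variant Proteogenomic Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variant- and gene-level association mapping between rare
    protein-coding variants and plasma protein abundances. Implements an
    exome-wide association scan (ExWAS) with genotypic, dominant and
    recessive encodings, declarative qualifying-variant collapsing models
    with dominant, recessive (compound-heterozygote and X-hemizygote)
    carrier construction, pQTL-informed augmented collapsing models for
    phenome-wide association studies, cis/trans pQTL classification,
    n-of-1 permutation calibration of significance thresholds, genomic
    inflation estimation, and clonal-haematopoiesis proteomic association
    from somatic call tables. Ships a synthetic cohort generator with
    planted ground truth so that every stage is testable without
    access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    withr
Config/testthat/edition: 3
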