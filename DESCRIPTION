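Package: molqtl
Title: Molecular QTL Discovery with Permutation-Based Multiple-Testing Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical toolkit for mapping molecular quantitative trait
    loci (molQTLs). Implements cis-QTL scans with beta-approximated
    permutation p-values for single phenotypes and phenotype groups,
    stepwise conditional mapping of multiple independent signals,
    genome-wide trans-QTL scans with full-permutation and approximate
    beta-based false-discovery-rate control, density and enrichment of
    functional annotations around QTLs, genotype-versus-sequence sample
    concordance checks, and a deterministic simulator producing genotypes,
    phenotypes, annotations and allele counts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
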