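Package: duckgwas
Title: Linear Mixed-Model GWAS for Egg-Production Traits with Haplotype
    Sharing and Bootstrap Reliability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end genome-wide association pipeline for
    egg-production traits in laying ducks (age at first egg and cumulative
    egg numbers), built around a univariate linear mixed model with a
    genomic kinship matrix. Provides a calibrated synthetic-data generator
    (founder-mosaic phased genotypes with linkage-disequilibrium blocks and
    correlated polygenic traits), VCF input with site-level quality control,
    restricted maximum-likelihood variance components and SNP heritability,
    Wald association scans, rank-based empirical false discovery rates and
    genomic-inflation diagnostics, linkage-disequilibrium delineation of
    confidence intervals around top signals, haplotype-sharing group tests,
    and a bootstrap resampling test of regional signal reliability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
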