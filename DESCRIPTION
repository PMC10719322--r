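Package: mwascan
Title: Methylome-Wide Association Scans from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for blood methylome-wide association studies (MWAS) driven
    by genome-wide association study (GWAS) summary statistics. Trains cis
    DNA-methylation genetic prediction models with the elastic net (with an
    optional meQTL pre-filter), tests genetically predicted methylation
    against GWAS summary statistics with an S-PrediXcan-style Z statistic,
    fine-maps associated CpG sites within linkage-disequilibrium blocks to
    posterior inclusion probabilities and credible sets, annotates CpG sites
    into functional categories and tests category enrichment, and
    triangulates methylation-expression-risk direction consistency. Includes
    a synthetic-data generator (LD-correlated genotypes, cis-meQTL
    architecture, methylation-mediated expression, liability-threshold
    case-control summary statistics) so the whole pipeline is testable
    without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    limma,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
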