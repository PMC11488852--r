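Package: protoy
Title: Proto-Y Chromosome Trans-Regulation of Gene Expression and Male Courtship
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying how young proto-Y chromosomes act
    as trans regulators of gene expression and male courtship behavior in the
    house fly (Musca domestica). Implements differential expression between
    Y(M) and III(M) males with empirical-Bayes moderated statistics, weighted
    gene co-expression networks with topological overlap and module eigengenes,
    a connection-score statistic linking transcripts to the Obp56h odorant
    binding protein family, chromosome enrichment tests, allele-specific
    expression calls from diagnostic SNP read depths, resampling fold-change
    nulls for ortholog sets, degree-day accounting, and censored
    copulation-latency survival models. A synthetic-data generator emulates
    the statistical structure of the study designs for testing and power
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
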