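Package: trendscreen
Title: Trend-Test-Based Feature Screening for Case-Control SNP Data
Version: 0.1.0
Authors@R:
    person("trendscreen", "developers", email = "trendscreen@example.org",
           role = c("aut", "cre"))
Description: Sure-independence screening of single nucleotide polymorphisms
    against a binary case-control phenotype using sample-size-adjusted
    Cochran-Armitage trend statistics under the recessive, additive and
    dominant score vectors (REC-SIS, ADD-SIS, DOM-SIS) and their model-robust
    maximum (MAX-SIS), plus a Pearson chi-square comparator.  Includes a
    trinomial genotype-count simulator for recessive, additive, dominant and
    mixed penetrance models, replicated evaluation of per-SNP and
    all-SNP selection proportions, genotype TSV/VCF readers with the standard
    missingness, genotype-class and minor-allele-orientation filters, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    stats,
    utils
Suggests:
    S4Vectors,
    VariantAnnotation,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
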