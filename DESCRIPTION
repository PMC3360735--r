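Package: bfdprior
Title: Literature-Informed Priors and Bayes False Discovery Probabilities for GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Derives per-SNP prior probabilities of association from keyword
    evidence in per-gene literature corpora and combines them with GWAS summary
    statistics into Bayes False Discovery Probabilities (BFDP). Genes are
    classified by the presence of three tiers of disease keywords in their
    linked abstracts (matched as Porter stem sequences), SNPs inherit pooled
    evidence from genes within a mapping window, and the resulting evidence
    categories translate category counts plus an assumed number of true
    susceptibility SNPs into prior odds of the null hypothesis. The package
    computes Wakefield's approximate Bayes factor and the BFDP per SNP, the
    statistical power of selecting SNPs below a BFDP threshold via the
    non-central chi-square distribution, and supports two-phase
    (discovery/replication) ranking workflows. A frequentist layer provides
    per-allele trend logistic regression on genotype counts, Hardy-Weinberg
    quality-control filters, Cochran's Q heterogeneity tests and the genomic
    inflation factor. A synthetic-data module generates corpora and
    case-control genotype counts with known ground truth and drives a
    subsampling experiment comparing p-value and BFDP rankings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
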