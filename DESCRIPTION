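Package: iSetR
Title: Interaction Set Tests for Genotype-Context Interactions with
    Multivariate Linear Mixed Models
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Set-based tests for interactions between sets of genetic
    variants and categorical contexts (environments, stimuli, sexes) using
    multivariate linear mixed models with Kronecker-structured covariance.
    Implements the mtSet association test, the iSet interaction test and the
    iSet-het test for heterogeneity of the local genetic architecture between
    contexts, with empirical p-values obtained from permutation and
    parametric-bootstrap null distributions pooled across regions. Also
    provides variance decomposition of regional genetic effects into
    persistent, rescaling and heterogeneity components, best linear unbiased
    prediction of cis genetic values, a single-variant interaction baseline,
    phenotype preprocessing (quantile normalization, covariate regression,
    genotype principal components), sliding-window genome scans over VCF or
    dosage inputs, and a synthetic-data framework (mosaic genotypes with
    local linkage disequilibrium, structured confounding, configurable
    interaction architectures) for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    vcfR,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
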