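Package: gremlpower
Title: Power and Sampling Variance for SNP-Based Estimates of Heritability and Genetic Correlation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Closed-form approximations to the sampling variance of
    SNP-based (GREML) estimates of heritability and genetic correlation in
    conventionally unrelated samples, for quantitative traits and for
    ascertained case-control studies via the liability-threshold
    transformation. Statistical power and minimum sample sizes are obtained
    from the non-central chi-squared distribution of the Wald test.  The
    package also provides genomic relationship matrix (GRM) construction
    and GCTA-format text I/O, Haseman-Elston pairwise-product regression
    estimators of heritability and genetic covariance, and a synthetic-data
    replicate harness that verifies every variance approximation by
    simulation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
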