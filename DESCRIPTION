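Package: dynlr
Title: Dynamic Likelihood-Ratio Thresholds for Forensic DNA Database Searching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact discrete distributions of multi-locus log10 likelihood
    ratios for short-tandem-repeat (STR) profile comparisons under the
    Balding-Nichols population-substructure model, computed by FFT
    convolution of single-locus probability mass functions.  The tail of
    the distribution is inverted into loci-set-specific likelihood-ratio
    thresholds that cap the expected number of adventitious (false
    positive) matches in a database search of any size, via a Poisson
    model of the false-positive count.  Includes a synthetic-population
    simulator (Dirichlet-structured subpopulations, degraded stains,
    Mendelian relatives), an exact-match search engine with dynamic,
    static-LR and locus-count filtering, and evaluation machinery
    (calibration against Poisson bounds, ROC comparison of filtering
    methods, Monte-Carlo convergence checks, Gaussian-baseline tail
    analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
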