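Package: twinpath
Title: Liability-Threshold Twin Models for Binary Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Biometric modelling of binary twin data on the liability scale:
    maximum-likelihood tetrachoric correlations (phenotypic, intraclass, and
    cross-twin cross-trait), univariate ACE/ADE-family model fitting with
    quantitative sex-limitation tests using opposite-sex dizygotic pairs,
    trivariate Cholesky, independent-pathway and common-pathway models
    estimated by full-information maximum likelihood over response-pattern
    frequencies, AIC/BIC model selection, and decomposition of fitted models
    into genetic and environmental correlations and common/specific variance
    shares. Includes a twin-cohort simulator that generates binary phenotypes
    by thresholding multivariate normal liabilities under any supported
    generating model, and an orchestrated analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    mvtnorm,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'cohort.R'
    'structure.R'
    'simulate.R'
    'tetrachoric.R'
    'likelihood.R'
    'fit.R'
    'decompose.R'
    'pipeline.R'
    'twinpath-package.R'
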