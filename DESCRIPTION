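Package: expotraj
Title: Latent-Class Trajectories of Lifetime Exposure Intensity and Disease Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage analysis of lifetime exposure histories in case-control
    studies. Stage 1 fits latent class mixed models (LCMM) to annual
    exposure-intensity series on a backward time axis (years before the index
    date), using a monotone I-spline link to normalise right-skewed,
    zero-heavy intensities, natural cubic splines of time, class-specific
    random intercepts, and a multi-start maximum-likelihood grid; models with
    one to six classes are compared by BIC, AIC, relative entropy and the
    posterior classification table. Stage 2 estimates the association between
    trajectory-class membership and a binary outcome by posterior-probability
    weighted logistic regression with a never-exposed reference class,
    fractional-polynomial confounder adjustment and cluster-robust (sandwich)
    variances. Includes job-exposure-matrix exposure assessment (annual
    levels, cumulative index of exposure), the comprehensive smoking index,
    an a priori low-exposure partition, and a synthetic-data generator with
    known latent-class structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    jsonlite,
    sandwich,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
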