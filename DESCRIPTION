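Package: bnsens
Title: Structural Sensitivity Analysis for Discrete Bayesian Network Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the diagnostic accuracy of discrete
    Bayesian-network classifiers degrades under systematic structural errors.
    Provides exact inference by variable elimination, forward sampling,
    maximum-likelihood/Dirichlet-smoothed parameter fitting, augmented naive
    Bayes construction, value-of-information node ranking by mutual
    information, Euclidean arc-strength edge ranking, and mutilation
    trajectories (node removal, edge removal, edge reversal with a
    cycle-avoiding postponement queue) that refit parameters after every edit
    and record resubstitution accuracy and one-vs-rest AUC for the most
    prevalent class. Includes a synthetic generator of diagnostic
    gold-standard networks and record tables emulating small categorical
    medical data sets, and XMLBIF/CSV interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    xml2
Suggests:
    ggplot2,
    jsonlite,
    knitr,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
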