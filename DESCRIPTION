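Package: commonbase
Title: Common Base Analysis of Relative Gene Expression from qPCR
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Relative quantification of qPCR experiments with the Common Base
    Method: per-well quantification cycles (Cq) are weighted by the logarithm
    of their amplification efficiencies so that all normalization, averaging
    and statistics happen on a common log scale. Supports multiple reference
    genes via arithmetic means in log scale, unpaired (Welch) and paired
    t-tests, one-factor ANOVA with additive blocking on plates or individuals,
    Bonferroni post-hoc comparisons, and back-transformation of log-scale
    estimates and confidence intervals to expression ratios. Includes a
    synthetic plate generator with known ground truth for power, coverage and
    calibration studies, and a demonstrator of why t-tests applied directly to
    ratio-scale values are direction-dependent.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
biocViews: qPCR, GeneExpression, Normalization, StatisticalMethod
RoxygenNote: 7.3.3
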