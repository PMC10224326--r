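Package: ccindex
Title: Composite Coverage Index Analysis for Complex Health Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Composite Coverage Index (CCI), the weighted average
    coverage of eight preventive and curative interventions along the maternal
    and child care continuum, from individual-level household-survey microdata,
    and carries the full design-based inferential chain used in maternal and
    child health monitoring: Taylor-linearised estimation of proportions for
    two-stage stratified cluster samples, Rao-Scott second-order corrected
    chi-square tests, design-based rank-sum tests, survey-weighted logistic
    regression with sandwich variance and backward AIC selection,
    Hosmer-Lemeshow calibration checks, global and local Moran spatial
    autocorrelation with permutation inference, and weighted Gini
    classification trees. Includes a synthetic-data generator emulating
    two-stage stratified cluster sampling over eight administrative regions
    with known ground truth, so the whole pipeline is testable without
    restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    MASS,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    rpart
Config/testthat/edition: 3
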