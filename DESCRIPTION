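Package: heipop
Title: Population-Ratio HEI-2015 Scoring of Foods by Food Outlet with Replicate-Weight Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores any weighted mix of reported foods with the Healthy Eating
    Index 2015 (HEI-2015) using the population ratio method: weighted totals of
    food-pattern equivalents are converted to energy densities and scored
    piecewise-linearly against the HEI-2015 standards. Supports stratification
    of 24-hour dietary recall microdata by the outlet where each food was
    obtained (stores, schools, full-service and quick-service restaurants),
    Fay-adjusted balanced repeated replication (BRR) standard errors for any
    group statistic, pairwise outlet contrasts, cross-cycle linear trend tests,
    letter grading, calorie-share tables, and radar plots of component-score
    patterns. Includes a synthetic recall-data generator with known ground
    truth so the whole pipeline can be exercised without survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    foreign
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
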