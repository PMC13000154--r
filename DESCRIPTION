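Package: shatterscan
Title: Record-Shattering Compound Drought Analysis for Large Climate Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify the probability of record-shattering droughts
    that compound across major crop-producing regions, using single-model
    initial-condition large ensembles (SMILEs) of surface soil moisture.
    Implements percentile-threshold drought classification against a pooled
    preindustrial baseline, regional and global drought-area series,
    record-breaking and record-shattering event detection with configurable
    exceedance margins, 31-year moving-window probability estimation,
    moving-window detrending experiments that stationarize the mean and/or
    standard deviation of soil moisture, leave-one-region-undetrended trend
    attribution, coincidence analysis of global events with regional
    record-shattering and moderately extreme droughts, evaluation diagnostics
    (drought-area trends and interannual variability), and a synthetic
    large-ensemble generator with prescribed regional trends for fully
    reproducible desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    ncdf4,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    tidyr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
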