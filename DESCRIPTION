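Package: clocktol
Title: Tolerance of Epigenetic Clocks to Error in Calibration Ages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation pipeline quantifying how much chronological-age error
    in the calibration data of an elastic-net epigenetic clock can be
    tolerated before age prediction degrades detectably. Generates synthetic
    DNA methylation datasets with age-informative CpG sites, injects bounded
    symmetric relative error into training ages, refits penalized-regression
    clocks across an error sweep, and locates tolerance thresholds with
    unpaired t-tests, Cohen's d effect sizes, and a fitted linear
    effect-size model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
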