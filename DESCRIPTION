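Package: tenamericas
Title: Life Expectancy Disparities Across County-Race Population Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Partitions a national population into ten mutually exclusive
    county-by-race/ethnicity groups ("Americas") and estimates life
    expectancy at birth, partial (temporary) life expectancies, and
    remaining life expectancy at age 85 from tabulated deaths and
    population counts.  Death tabulations are corrected for race/ethnicity
    misclassification on death certificates using simulated ratio draws,
    population series are harmonised across census bases, and uncertainty
    is propagated by Monte-Carlo simulation through abridged life tables.
    Includes a synthetic vital-statistics generator so the full pipeline
    can be exercised and validated without access to restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
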