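Package: aefitrends
Title: Social-Media Surveillance of Vaccine Adverse Effects and Sentiment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for pharmacovigilance on social-media
    post corpora: two-step thematic keyword filtering (pandemic terms, then
    vaccine and manufacturer terms), grouped counting of adverse-effect-
    following-immunization (AEFI) mentions over two-week bins with per-user
    activity statistics, and a hybrid ensemble sentiment classifier that
    combines two weighted lexicon polarity scorers with a categorical model
    through an if-else rule, aggregated into weekly sentiment trend series.
    Includes a seeded synthetic-corpus generator with log-normal per-user
    activity and ground-truth labels, so the whole pipeline is testable
    without redistributing platform data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
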