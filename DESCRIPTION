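Package: thermdecay
Title: Thermal Decay Rate Index from Day/Night Land Surface Temperature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the remotely sensed thermal decay rate index (R_dk),
    a Newton's-law-of-cooling parameterization of paired daytime and
    nighttime land surface temperatures, and provides the surrounding
    analysis stack: per-pixel annual aggregation of decay rates on gridded
    temperature stacks, reduced major axis regression for cross-platform
    comparison, Pearson/Spearman cross-correlation tables, and per-pixel
    Mann-Kendall trend classification. A Newtonian diurnal-cooling scene
    simulator with satellite-like overpass sampling, observational noise,
    cloud masking, and injected multi-year trends makes every stage of the
    pipeline testable end-to-end without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
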