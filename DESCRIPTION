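Package: phenodesert
Title: Phenocam Greenness Processing for Low-Amplitude Dryland Vegetation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes repeat digital camera imagery of sparse, semi-arid
    vegetation into phenological metrics. Extracts green chromatic coordinate
    (GCC) time series from polygon regions of interest, cleans them with a
    filter chain that includes an automated snow/night filter based on
    breakpoint detection in the cumulative distribution of GCC, fits the Gu
    double-logistic model with residual-resampling uncertainty to date the
    upturn, stabilization, downturn and recession of the growing season, and
    maps per-pixel phenology with changepoint separation of vegetation from
    bare-ground interspace. Includes a synthetic scene generator with known
    ground truth for validating every stage.
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
    jpeg,
    jsonlite,
    minpack.lm,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    patchwork,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
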