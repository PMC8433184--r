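Package: embryochip
Title: Automated Phenotyping of C. elegans Embryos in Microfluidic Incubator Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated analysis of time-lapse microscopy of
    Caenorhabditis elegans embryos developing inside microfluidic incubator
    traps. Locates incubators in a field of view, crops per-embryo image
    patch series, classifies developmental stage from patches (empty
    incubator, pre-bean, bean), derives a frame-differencing mobility trace
    to call dead versus alive embryos and the twitching onset, assembles
    per-embryo state labels (Normal, Dead, Unclear, Late Hatching, Empty)
    with bean/twitch/hatch transition times, quantifies background-normalized
    embryo fluorescence from a masked reporter channel, and aggregates
    cohorts into viability fractions, interval phenotypes and a normalized
    clustergram. Includes a seeded synthetic chip time-lapse generator with
    full ground truth so that every stage of the pipeline is testable
    without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    nnet,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    ggplot2,
    generics,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
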