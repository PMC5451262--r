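Package: iftpool
Title: Queue Model of Intraflagellar Transport Train Assembly with Virtual
    Photobleaching Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulator of the intraflagellar transport (IFT)
    protein life cycle in biflagellate cells: recruitment from the cell body
    into a basal-body assembly queue, anterograde transit, tip turnaround,
    retrograde return, and open or semi-open recycling, with per-copy
    photobleach state. A virtual TIRF microscope renders ground-truth
    simulations into kymograms and frame stacks under spot-bleach, FLIP and
    whole-flagellum-bleach protocols, and a quantification toolkit implements
    the matching estimators: intensity traces with frame-by-frame control
    normalization, two-line FRAP recovery fitting, FLIP slope and plateau
    analysis, shear-and-sum trajectory detection, traffic statistics,
    post-bleach gap measurement and per-departure pool drops. Orchestrated
    in-silico experiments reproduce the photobleaching assays end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
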