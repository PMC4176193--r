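Package: pericore
Title: Pericentromeric Probe Panels and Marker Chromosome Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design junction-bridging pericentromeric BAC probe panels from
    genome annotation tracks, and characterize small supernumerary marker
    chromosomes (sSMCs) from per-probe FISH signal patterns: heterochromatic
    versus euchromatic classification, breakpoint interval inference, per-
    segment dosage, euchromatic content bounds, mosaicism estimation with
    exact confidence intervals, array-CGH breakpoint refinement, and
    critical-region based phenotype risk labels. Includes a seed-controlled
    simulator of toy genomes, clone libraries and marker-chromosome
    observations with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
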