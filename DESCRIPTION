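Package: rhizokde
Title: Kernel Density Mapping of Bacterial Colonization in the Rhizosphere Pore Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the establishment of bacteria in the rhizosphere pore
    space from segmented confocal image tiles. Decomposes class masks
    (mobile bacteria, root biofilm, particle biofilm) into patches by
    watershed, attaches distance-transform covariates (distance to particle
    surface, to the root surface and from the root tip), and estimates
    fluorescence-weighted occupancy densities with finite-support top-hat
    (Parzen) kernels, together with a pore-space null model, a linear
    fluorescence-to-cell-count calibration, and per-root colonization
    statistics (colonization states, cell-density profiles along the root,
    biofilm-to-tip distances). Ships a seeded synthetic microcosm generator
    so the whole pipeline is testable without microscope data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
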