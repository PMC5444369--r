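Package: witomi
Title: Realized Niche Decomposition into Subset-Specific Subniches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordination-based analysis of species' ecological niches and their
    decomposition into subset-specific realized subniches. Fits the outlying
    mean index (OMI) ordination, which finds combinations of environmental
    variables maximizing average species marginality, and refines it with
    within-subset marginality indexes (WitOMI) measured from the overall
    habitat centroid G and from each subset centroid G_K. Provides Monte-Carlo
    permutation tests for subset habitat conditions and subniche marginalities,
    minimum-convex-polygon niche envelopes with the biological constraint S_B
    (the unoccupied share of the existing fundamental subniche S_P), a
    synthetic community generator with known niche structure, tidy() and
    glance() methods, ggplot2 graphics, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
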