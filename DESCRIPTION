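Package: ribdmap
Title: Relative Identity-by-Descent Mapping of Adaptive Introgression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps genomic regions under adaptive introgression in an admixed
    population with two source breeds by aggregating pairwise
    identity-by-descent (IBD) segments into per-window sharing fractions.
    For each 10 kbp window the relative IBD score rIBD = IBD_S1 - IBD_S2
    contrasts sharing with the two source breeds; normal-theory cut-offs at
    mean plus or minus k standard deviations flag significantly introgressed
    regions. Includes readers for Refined-IBD-style segment files, a
    synthetic IBD-segment generator with known ground-truth local ancestry,
    significance summaries with region merging, genome-track and histogram
    plots, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    IRanges,
    S4Vectors,
    ggplot2,
    optparse,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
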