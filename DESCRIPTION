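Package: chronoscreen
Title: Pooled Barcode Screen Analysis for Yeast Chronological Lifespan
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pooled deletion-barcode chronological
    lifespan screens in yeast. Builds per-strain aging profiles (log2 tag
    intensity ratios relative to a reference day) from barcode array
    intensities, applies background-tag and replicate-concordance (RSME)
    quality filters, clusters averaged profiles with K-means and classifies
    clusters as short-lived, long-lived or neutral, tests each strain for a
    consistent time-course change with a natural-cubic-spline F statistic,
    pooled permutation null and Storey q-values, reconstructs per-strain
    survival curves by multiplying fold ratios by pool colony-forming-unit
    counts, estimates mean lifespan by Boltzmann sigmoidal fitting and
    survival-curve area, and performs hypergeometric term enrichment.
    Includes a synthetic pooled-screen generator with planted ground truth so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    pracma,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
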