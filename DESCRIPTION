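Package: expalm
Title: Analysis of Expansion-Microscopy PALM Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of single-molecule localization
    microscopy (PALM) data from physically expanded specimens. Provides
    readers and writers for localization tables and multi-page TIFF
    stacks, sample-drift estimation and correction by sub-stack
    cross-correlation, tracked frame-to-frame shifts or fiducial markers,
    localization-precision estimation by nearest-neighbour analysis
    (NeNA), super-resolution image rendering, expansion-factor and
    protein-retention quantification, a density-matched
    nearest-neighbour statistic for assessing isotropy of expansion, and
    a ground-truth-known synthetic data generator emulating expanded and
    non-expanded fission-yeast PALM datasets so that every stage of the
    pipeline can be validated by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
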