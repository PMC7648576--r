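Package: asympart
Title: Quantification of Asymmetric Transcription-Factor Partitioning in
    Dividing Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the asymmetric partitioning of a nuclear-localized
    fluorescent reporter (such as Ace2-YFP) between the nascent mother and
    daughter nuclei of dividing budding yeast. Segments nuclei from a
    histone-marker channel, estimates local background from a morphological
    ring around each nucleus, computes background-corrected nuclear
    intensities, calibrates a reporter-presence threshold from an S-phase
    reference population, classifies telophase pairs as asymmetric,
    symmetric or reporter-negative, and computes the asymmetry index and
    cumulative pair intensity. Includes a seeded synthetic-scene generator
    with full ground truth for validation, the nonparametric statistics used
    for screen-scale comparisons (Fisher's exact test, Kruskal-Wallis,
    Wilcoxon rank sum, Wilson intervals), and tabulation plus functional
    enrichment of genetic-screen hit tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
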