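Package: karyodens
Title: Image Cytometry of Chromatin Condensation by Feulgen Densitometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative image-cytometry toolkit for studying chromatin
    remodeling in cultured cells, as induced for instance by histone
    deacetylase inhibitors. Converts microscope images of Feulgen-stained
    nuclei to per-pixel absorbance, segments nuclei by a background
    absorbance rule, and computes per-nucleus karyometric parameters
    (integrated absorbance, nuclear and condensed-chromatin areas, Sc%,
    Ac% and the average absorption ratio AAR). Provides population-level
    statistics (Mann-Whitney and Student t comparisons, Feulgen-DNA
    C-class ploidy histograms, Sc% versus AAR phenotype scatter diagrams,
    mitotic and cell-death index tables), quantitative TUNEL spot-area
    scoring with weak/moderate/strong ranking, and a seeded
    synthetic-nucleus generator with known ground truth so the full
    pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    ggplot2,
    jsonlite,
    rlang,
    tiff,
    png,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
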