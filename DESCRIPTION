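Package: dropcurve
Title: Dropout Curves and Attrition Analysis for Internet-Based Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify and visualize participant dropout (attrition)
    in Internet-based experiments and surveys. From a wide participant-by-item
    response table, derives a per-participant dropout index (position of the
    last answered item), per-condition attrition curves, item-level
    contingency statistics (chi-square tests and all-pairs odds ratios),
    Kaplan-Meier retention curves with G-rho family (weighted log-rank)
    difference tests, and a Kolmogorov-Smirnov comparison of the two most
    extreme conditions. Includes a seeded synthetic-data generator for
    discrete-time dropout processes, publication-ready ggplot2 figures with
    colorblind-safe palettes, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ggplot2,
    survival,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
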