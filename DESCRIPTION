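Package: heatcraft
Title: Scriptable Heatmap Engine with Clustering and Raster Export
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable engine for expression heatmaps: reads numeric
    tables from CSV/TSV/Excel sheets, rescales values to [0,1] by global
    linear or logarithmic min-max normalization, maps them through a
    discretized 768-row tricolor lookup table, optionally reorders rows
    and columns by agglomerative hierarchical clustering (average, minimum
    or maximum linkage over seven distance metrics, including Pearson,
    Spearman and Kendall correlation distances) or seeded k-means, and
    rasterizes publication-quality figures with dendrograms and a color
    bar, exported as PNG or TIFF at 72/300/600 dpi. Includes a seeded
    synthetic expression-matrix generator with planted cluster structure
    and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    readxl,
    png,
    jsonlite,
    yaml,
    optparse,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    mclust
Config/testthat/edition: 3
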