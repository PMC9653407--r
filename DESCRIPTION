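Package: cidmem
Type: Package
Title: Distance-Coupled Transcriptional Memory in Cancer-Immune Cell Doublets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for microfluidic co-incubation experiments in
    which single natural killer (NK) cells and single cancer cells are captured
    as doublets, imaged over time for cell-cell distance, and profiled by
    terminal RNA sequencing. Provides chamber classification and quality-control
    filtering of cells and genes, the gene-by-timepoint Pearson correlation map
    linking temporally tracked distances to terminal expression, retention and
    hierarchical clustering of memory genes into modules, a Welch test relating
    module membership to mRNA half-life, a ligand-receptor co-expression screen
    specific to doublets, differential expression between killing and
    non-killing doublets, and a fully parameterised synthetic-data generator
    with ground truth for benchmarking every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    yaml,
    ggplot2,
    pheatmap,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
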