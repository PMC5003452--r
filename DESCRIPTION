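Package: xspecies
Title: Cross-Species Microarray Probe Masking and Single-Feature
    Polymorphism Screening
Version: 0.1.0
Authors@R:
    person("Maintainer", "Xspecies", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for genomic-DNA-based probe selection on heterologous
    Affymetrix oligonucleotide arrays (the "Xspecies" approach). Reads
    text-format CEL and CDF files, background-corrects and
    quantile-normalizes probe-level intensities, computes probe-pair and
    probe-set retention curves over a grid of candidate cut-offs, and
    locates the knee of the retention curve by automated threshold mapping
    (orthogonal projection, fuzzy c-means clustering with cluster-validity
    indices, and interpolation), returning a suggested cut-off with target
    and tolerance intervals. Writes species-specific masked CDF files.
    Screens four-chip single-trait bulked-segregant designs (two parents,
    two F2 bulks) for single-feature polymorphisms via dual fold-change
    analysis and probe-wise one-sample statistical tests, with
    Benjamini-Hochberg correction, volcano-style filters, Euler-diagram
    partitioning and a candidate-selection strategy. Includes a
    synthetic-data generator that emulates the four-chip gDNA design with
    planted polymorphisms, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
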