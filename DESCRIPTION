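Package: beadbench
Title: Factorial Evaluation of Normalization and Differential Expression
    Strategies for Illumina Bead-Summary Microarrays
Version: 0.1.0
Authors@R:
    person("Array", "Methods", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for benchmarking how normalization strategies (none,
    average, cubic spline, quantile, rank invariant) interact with
    differential-expression approaches (pooled-variance t test, a
    three-component error-model z test, and the combinatorial Max Cover
    (alpha,beta)-k feature-set selector) on Illumina bead-summary
    expression data dominated by small (<2-fold) changes.  Includes a
    bead-summary reader/writer for GenomeStudio-style tab-delimited
    exports, empirical detection p-values against negative-control
    probes, entropy/MDL (Fayyad-Irani) discretization, probe-set
    concordance statistics (NOG/POG; full/partial/no concordance),
    hypergeometric pathway over-representation, a synthetic two-class
    bead-summary data generator with planted truth, and a factorial
    benchmark driver with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
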