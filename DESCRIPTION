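Package: tebench
Title: Benchmark Simulation and Evaluation for Transposable Element
    Insertion Callers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Toolkit for benchmarking short-read transposable element (TE)
    insertion callers on synthetic data. Constructs genomes carrying single
    LTR-retrotransposon insertions with 5-bp target site duplications placed
    upstream of tRNA genes in tRNA orientation, simulates paired-end
    Illumina-like reads at a stated coverage and base error rate,
    standardizes caller predictions into a common zero-based BED6 scheme,
    and evaluates predictions against the insertion truth: window-based
    accuracy at multiple thresholds, recurrent false-positive filtering,
    cross-method concordance (Venn) sets, positional metaplots around
    insertion sites and tRNA starts, predicted-TSD-length distributions,
    and tRNA-region enrichment tables. A built-in fixture generator and
    parameterized mock callers make every analysis reproducible without
    external data or tools.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
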