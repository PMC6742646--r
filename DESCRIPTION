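Package: edgoburden
Title: Edgotyping Pipelines: Clone Calling, Interaction Perturbation
    Networks, and Per-Genome Disruptive-Variant Burden
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computational core of a population-scale edgotyping study:
    calling engineered mutant clones from pooled next-generation sequencing
    read counts, calling and classifying protein-interaction disruptions
    from yeast two-hybrid growth readouts, extrapolating a per-genome
    disruptive-variant burden from allele-frequency-stratified disruption
    rates, scoring dual-fluorescence protein-stability assays, and placing
    disruptive variants in evolutionary and structural context
    (Jensen-Shannon divergence conservation, Fay and Wu's H selection
    scans, interface and duplicate-gene classification). Includes a
    synthetic-data generator with planted ground truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
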