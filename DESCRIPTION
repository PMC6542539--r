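Package: aarsrip
Title: RIP-Seq Enrichment, Binding-Site Mapping and Anticodon-Mimic
    Scanning for mRNA-Binding Aminoacyl-tRNA Synthetases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for RNA immunoprecipitation sequencing
    (RIP-seq) of tagged RNA-binding proteins against an untagged bead
    background: reads-per-million normalization, input-coverage filtering,
    per-gene RIP efficiency with background correction, deterministic
    ranking, and boxplot-style 1.5-IQR target calling with exclusive and
    shared (Venn-region) target sets. Also localizes binding regions from
    tiling-amplicon fragmentation-RIP signals, scans coding sequences for
    anticodon-like triplets presented in hairpin loops using Nussinov
    base-pair maximization with an exhaustive enumeration oracle, checks
    mutation synonymy under the standard genetic code, and classifies
    point-mutation effects on the stem-loop element. Seeded negative
    binomial simulators generate count tables, tiling panels and
    mimic-bearing coding sequences with known ground truth so the whole
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    readxl,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
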