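Package: azasynergy
Title: Drug-Combination Synergy, Pooled shRNA Screen, SLAM-Seq and
    Nascent-Proteome Analysis for Azacitidine Combination Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for four computational procedures used in
    studies of azacitidine drug combinations in leukemia cells: gene-level
    hit calling from pooled shRNA loss-of-function screens with a
    sign-consistency trend rule and permutation significance; median-effect
    dose-response fitting and Chou-Talalay combination-index scoring of drug
    pairs; nascent-transcript quantification from SLAM-seq T>C-conversion
    read counts with negative-binomial differential calling; and a
    MaxQuant-style protein-group filter cascade with PSM-reduction calls and
    transcript-protein overlap statistics. Includes synthetic-data
    generators with planted ground truth for every input type, so each
    stage is exercisable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
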