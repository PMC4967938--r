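Package: pathconcord
Title: Pathway-Level Concordance of Animal Models and Human Disease via Gene Set Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding which animal model best mimics a human disease at the
    pathway level. Implements two-class gene set enrichment analysis (signal-to-noise
    ranking, weighted Kolmogorov-Smirnov running-sum statistic, gene-set permutation
    null, normalized enrichment scores and permutation-based FDR), three-state
    per-pathway regulation calls (up, down, null at FDR <= 0.25), and pairwise
    model concordance measured by positive and negative predictive values against a
    chance baseline with 3x3 contingency chi-squared tests. Includes species-group
    statistics (Kruskal-Wallis with Dunn's post-hoc test and Bonferroni correction,
    two-sample proportion tests), readers for GMT/GCT/CLS/TSV formats, probe-to-symbol
    collapse and mouse-to-human ortholog mapping, and a synthetic expression-data
    generator with known pathway-level ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), withr, fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
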