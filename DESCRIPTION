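Package: crosshub
Title: Cross-Cohort Differential Expression, Overlap and Consensus Hub-Gene Detection
Version: 0.1.0
Authors@R:
    person("crosshub", "developers", email = "crosshub@example.org", role = c("aut", "cre"))
Description: A desk-scale systems-biology pipeline for disease-comorbidity
    transcriptomics: per-cohort differential expression (empirical-Bayes
    moderated t for array-like log intensities, negative-binomial Wald test
    with median-of-ratios normalisation for RNA-seq-like counts),
    multi-cohort Venn/k-of-n overlap, exact hypergeometric and Fisher/EASE
    over-representation analysis, confidence-thresholded protein-protein
    interaction networks, consensus hub-gene detection over degree,
    closeness, betweenness, stress and maximal-clique centrality rankings,
    and bipartite miRNA/transcription-factor/drug regulator layers.
    All inputs can be simulated with planted ground truth, so every stage
    is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
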