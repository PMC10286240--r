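#' Bundled reference top-20 centrality rankings
#'
#' Transcribed top-20 gene lists from a published COVID-19 x Alzheimer's
#' comorbidity network analysis, as ranked by betweenness, closeness,
#' degree and maximal clique centrality. `"module1"` is the network of
#' genes shared by >= 3 disease/tissue groups; `"module2"` the network of
#' genes carrying commonly enriched ontology terms. Used as worked-example
#' input to [consensus_hubs()].
#'
#' @param module `"module1"` or `"module2"`.
#' @return named list of four ordered character vectors (betweenness,
#'   closeness, degree, mcc).
#' @export
reference_rankings <- function(module = c("module2", "module1")) {
  module <- match.arg(module)
  path <- system.file("extdata", sprintf("reference_rankings_%s.tsv", module),
                      package = "crosshub", mustWork = TRUE)
  df <- read_tsv(path)
  lapply(df[c("betweenness", "closeness", "degree", "mcc")], as.character)
}

#' Bundled reference hub-gene lists
#'
#' The consensus hub genes the same study reports for each module (12 for
#' module 1, 17 for module 2; their union has 26 unique symbols).
#'
#' @return named list of character vectors, one per module.
#' @export
reference_hub_sets <- function() {
  path <- system.file("extdata", "reference_hub_sets.tsv",
                      package = "crosshub", mustWork = TRUE)
  df <- read_tsv(path)
  lapply(split(df$gene, df$module), as.character)
}
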