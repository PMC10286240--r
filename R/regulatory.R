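# Hub-gene-centered bipartite regulator layers: miRNA target filtering at the
# reliable-score cut (> 80), TF tables, drug-gene joins, degree filtering and
# the hub-regulator consensus over degree/betweenness/closeness/stress.

#' Regulator-target table constructor
#'
#' @param regulator,target character vectors.
#' @param kind `"miRNA"`, `"TF"` or `"drug"` per row (recycled).
#' @param score numeric prediction score per row; required in \[0, 100\] for
#'   miRNA rows, may be `NA` for TF/drug rows.
#' @return a `RegulatorTargetTable` (data frame).
#' @export
regulator_target_table <- function(regulator, target, kind = "miRNA",
                                   score = NA_real_) {
  df <- data.frame(regulator = as.character(regulator),
                   kind = as.character(kind),
                   target = as.character(target),
                   score = as.numeric(score),
                   stringsAsFactors = FALSE)
  bad <- !df$kind %in% c("miRNA", "TF", "drug")
  if (any(bad)) stop_parse(sprintf("unknown regulator kind '%s'", df$kind[bad][1]))
  mi <- df$kind == "miRNA"
  if (any(mi & (is.na(df$score) | df$score < 0 | df$score > 100)))
    stop_parse("miRNA rows require a score in [0, 100]")
  structure(df, class = c("RegulatorTargetTable", "data.frame"))
}

as_regulator_table <- function(df) {
  regulator_target_table(df$regulator, df$target,
                         kind = df$kind %||% "miRNA",
                         score = if ("score" %in% names(df)) df$score else NA_real_)
}

#' Filter miRNA rows to reliable prediction scores
#'
#' miRNA rows with score > `min_score` (strict comparison by default, so a
#' score of exactly 80 is dropped) are retained; TF and drug rows pass
#' through unfiltered. Idempotent.
#'
#' @param table a `RegulatorTargetTable`.
#' @param min_score reliability cut (default 80).
#' @param strict use strict `>` (default) rather than `>=`.
#' @return filtered `RegulatorTargetTable`.
#' @export
filter_reliable_targets <- function(table, min_score = 80, strict = TRUE) {
  mi <- table$kind == "miRNA"
  keep <- !mi | (if (strict) table$score > min_score else table$score >= min_score)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bipartite regulator-hub network
#'
#' Restricts a regulator-target table to edges whose target is a hub gene;
#' regulators left with zero surviving edges are dropped. Edges are
#' deduplicated.
#'
#' @param table a `RegulatorTargetTable`.
#' @param hubs character vector of hub gene symbols.
#' @param kind optional filter to one regulator kind.
#' @return a `BipartiteNetwork`: list with `left` (regulators), `right`
#'   (hub genes with >= 1 edge), `edges` (data frame regulator/target), `kind`.
#' @export
hub_regulator_network <- function(table, hubs, kind = NULL) {
  df <- as.data.frame(table, stringsAsFactors = FALSE)
  if (!is.null(kind)) df <- df[df$kind %in% kind, , drop = FALSE]
  df <- df[df$target %in% hubs, c("regulator", "target"), drop = FALSE]
  df <- unique(df)
  o <- order(df$regulator, df$target, method = "radix")
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  structure(list(left = sort_c(df$regulator), right = sort_c(df$target),
                 edges = df, kind = kind %||% "any"),
            class = "BipartiteNetwork")
}

#' Regulators reaching a minimum number of hub targets
#'
#' @param net a `BipartiteNetwork`.
#' @param min_targets minimum regulator degree; default 4, the literal
#'   reading of "more than three hub genes".
#' @return sorted character vector of regulator ids.
#' @export
regulators_by_min_targets <- function(net, min_targets = 4L) {
  deg <- table(net$edges$regulator)
  sort_c(names(deg)[deg >= min_targets])
}

# View a bipartite network as a simple undirected InteractionNetwork
# (regulators and genes both become vertices; unit edge scores).
bipartite_as_network <- function(net) {
  if (!nrow(net$edges))
    return(build_network(data.frame(from = character(0), to = character(0),
                                    score = numeric(0)), threshold = 0))
  build_network(data.frame(from = net$edges$regulator, to = net$edges$target,
                           score = 1, stringsAsFactors = FALSE),
                threshold = 0)
}

#' Consensus hub regulators
#'
#' Runs degree, betweenness, closeness and stress centrality on the
#' bipartite network viewed as a simple undirected graph, takes the top
#' `top_n` nodes per method, and keeps regulator-side nodes supported by at
#' least `min_methods` methods.
#'
#' @param net a `BipartiteNetwork`.
#' @param methods centrality methods (default degree, betweenness,
#'   closeness, stress).
#' @param top_n per-method list length (default 40).
#' @param min_methods minimum supporting methods (default 3).
#' @return sorted character vector of regulator ids.
#' @export
consensus_hub_regulators <- function(net,
                                     methods = c("degree", "betweenness",
                                                 "closeness", "stress"),
                                     top_n = 40L, min_methods = 3L) {
  if (!nrow(net$edges)) return(character(0))
  g <- bipartite_as_network(net)
  rankings <- centrality_rankings(g, methods)
  cons <- consensus_hubs(rankings, top_k = top_n, min_methods = min_methods)
  sort_c(intersect(cons$hubs, net$left))
}

#' Drug-gene interaction join
#'
#' Restricts a drug-kind regulator table to hub-gene targets; duplicate rows
#' are removed and the distinct-drug count reported as an attribute.
#'
#' @param table a `RegulatorTargetTable` (rows of any kind; only `drug` rows
#'   are joined).
#' @param hubs hub gene symbols.
#' @return a `BipartiteNetwork` with attribute `n_drugs`.
#' @export
drug_gene_join <- function(table, hubs) {
  net <- hub_regulator_network(table, hubs, kind = "drug")
  attr(net, "n_drugs") <- length(net$left)
  net
}

#' Per-regulator summary table
#' @param net a `BipartiteNetwork`.
#' @param consensus regulators selected by [consensus_hub_regulators()].
#' @return data frame regulator, n_hub_targets, consensus_member.
#' @export
regulator_summary <- function(net, consensus = character(0)) {
  deg <- table(net$edges$regulator)
  regs <- sort_c(names(deg))
  data.frame(regulator = regs,
             n_hub_targets = as.integer(deg[regs]),
             consensus_member = regs %in% consensus,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.BipartiteNetwork <- function(x, ...) {
  cat(sprintf("BipartiteNetwork [%s]: %d regulators x %d genes, %d edges\n",
              x$kind, length(x$left), length(x$right), nrow(x$edges)))
  invisible(x)
}
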