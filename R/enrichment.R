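# Over-representation analysis: exact hypergeometric upper tail computed in
# log space, the Fisher / EASE variants, gene-set enrichment over a GMT-style
# annotation table, and the cross-disease common-term gene selection.

validate_enrichment_query <- function(N, M, n, k) {
  if (anyNA(c(N, M, n, k)) || any(c(N, M, n, k) < 0) ||
      any(c(N, M, n, k) != round(c(N, M, n, k))))
    stop_config("N, M, n, k must be nonnegative integers")
  if (M > N || n > N) stop_config("M and n cannot exceed the universe size N")
  if (k > min(M, n)) stop_config("k cannot exceed min(M, n)")
  invisible(TRUE)
}

#' Exact hypergeometric upper-tail probability
#'
#' Probability of observing `k` or more annotated genes in a query of size
#' `n` drawn from a universe of `N` genes of which `M` are annotated:
#' `P(X >= k) = sum_{i>=k} C(M,i) C(N-M,n-i) / C(N,n)`, the complement of
#' the cumulative sum to `k - 1`. Computed by log-space summation
#' (`lchoose` + log-sum-exp) for numerical stability.
#'
#' @param N background universe size.
#' @param M genes annotated to the term.
#' @param n query-set size.
#' @param k annotated genes observed in the query.
#' @return the exact tail probability in \[0, 1\].
#' @export
hypergeom_tail <- function(N, M, n, k) {
  validate_enrichment_query(N, M, n, k)
  if (k <= 0) return(1)
  i <- k:min(M, n)
  lo <- max(0, n - (N - M))
  i <- i[i >= lo]
  if (!length(i)) return(0)
  lt <- lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)
  mx <- max(lt)
  min(1, exp(mx) * sum(exp(lt - mx)))
}

#' One-sided Fisher exact enrichment p-value, with EASE variant
#'
#' The one-sided Fisher p equals the hypergeometric upper tail at `k`.
#' The EASE score (a conservative variant used by annotation servers)
#' recomputes the tail after replacing `k` with `max(k - 1, 0)`, so
#' `p_EASE >= p_Fisher` always.
#'
#' @inheritParams hypergeom_tail
#' @param ease compute the EASE score instead of the plain Fisher p.
#' @return p-value in \[0, 1\].
#' @export
fisher_enrich <- function(N, M, n, k, ease = FALSE) {
  validate_enrichment_query(N, M, n, k)
  if (ease) k <- max(k - 1, 0)
  hypergeom_tail(N, M, n, k)
}

#' Annotation table constructor
#'
#' @param term character vector of term identifiers.
#' @param namespace one of `"BP"`, `"CC"`, `"MF"`, `"pathway"` per term.
#' @param genes list of character vectors of member genes.
#' @param description optional descriptions.
#' @return an `AnnotationTable` (data frame with a `genes` list column).
#' @export
annotation_table <- function(term, namespace, genes, description = NULL) {
  stopifnot(length(term) == length(namespace), length(term) == length(genes))
  ok <- namespace %in% c("BP", "CC", "MF", "pathway")
  if (!all(ok))
    stop_parse(sprintf("unknown namespace '%s'", namespace[!ok][1]))
  df <- data.frame(term = as.character(term),
                   namespace = as.character(namespace),
                   description = description %||% rep("", length(term)),
                   stringsAsFactors = FALSE)
  df$genes <- lapply(genes, function(g) sort_c(g))
  structure(df, class = c("AnnotationTable", "data.frame"))
}

#' Gene-set over-representation analysis
#'
#' One result row per annotation term with at least one query hit. P-values
#' are BH-adjusted across all tested terms; q-values are reported as the
#' BH-adjusted values. Results are sorted by ascending p with lexicographic
#' term tie-break.
#'
#' @param genes query gene set.
#' @param annotation an [annotation_table()].
#' @param background background gene universe (default: union of all
#'   annotated genes and the query).
#' @param method `"hypergeometric"` (default), `"fisher"` (identical tail)
#'   or `"ease"`.
#' @param alpha significance threshold recorded in the `significant` column
#'   (terms with raw p below it).
#' @return data frame: term, namespace, N, M, n, k, fold_enrichment, p,
#'   adj_p, q_value, significant.
#' @export
enrich_gene_set <- function(genes, annotation,
                            background = NULL,
                            method = c("hypergeometric", "fisher", "ease"),
                            alpha = 0.05) {
  method <- match.arg(method)
  if (is.null(background))
    background <- union(unlist(annotation$genes, use.names = FALSE), genes)
  background <- sort_c(background)
  genes <- unique(as.character(genes))
  outside <- setdiff(genes, background)
  if (length(outside)) {
    warning(sprintf("dropping %d query gene(s) outside the background (e.g. %s)",
                    length(outside), outside[1]), call. = FALSE)
    genes <- setdiff(genes, outside)
  }
  N <- length(background)
  n <- length(genes)
  empty <- data.frame(term = character(0), namespace = character(0),
                      N = integer(0), M = integer(0), n = integer(0),
                      k = integer(0), fold_enrichment = numeric(0),
                      p = numeric(0), adj_p = numeric(0),
                      q_value = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE)
  if (n == 0L || nrow(annotation) == 0L) return(empty)
  M <- vapply(annotation$genes, function(g) length(intersect(g, background)), integer(1))
  k <- vapply(annotation$genes, function(g) length(intersect(g, genes)), integer(1))
  keep <- k >= 1L
  if (!any(keep)) return(empty)
  res <- data.frame(term = annotation$term[keep],
                    namespace = annotation$namespace[keep],
                    N = N, M = M[keep], n = n, k = k[keep],
                    stringsAsFactors = FALSE)
  res$fold_enrichment <- (res$k / res$n) / (res$M / res$N)
  res$p <- mapply(function(M, k) {
    switch(method,
           hypergeometric = hypergeom_tail(N, M, n, k),
           fisher = fisher_enrich(N, M, n, k, ease = FALSE),
           ease = fisher_enrich(N, M, n, k, ease = TRUE))
  }, res$M, res$k)
  res$adj_p <- bh_adjust(res$p)
  res$q_value <- res$adj_p
  res$significant <- res$p < alpha
  res[order(res$p, res$term, method = "radix"), , drop = FALSE]
}

#' Commonly enriched terms between two enrichment results
#'
#' Intersects the significant terms (raw p < `alpha`) of two enrichment
#' result tables, keyed by namespace.
#'
#' @param results_a,results_b outputs of [enrich_gene_set()].
#' @param alpha significance threshold (default 0.05).
#' @return named list of term vectors, one per namespace present, with an
#'   attribute `counts` giving per-namespace totals.
#' @export
common_terms <- function(results_a, results_b, alpha = 0.05) {
  sig <- function(r) r[r$p < alpha, c("term", "namespace")]
  a <- sig(results_a); b <- sig(results_b)
  spaces <- sort_c(c(a$namespace, b$namespace))
  out <- lapply(spaces, function(ns) {
    sort_c(intersect(a$term[a$namespace == ns], b$term[b$namespace == ns]))
  })
  names(out) <- spaces
  attr(out, "counts") <- vapply(out, length, integer(1))
  out
}

#' Genes annotated to at least one common term
#'
#' The module-2 gene selection: differentially expressed genes that carry at
#' least one of the commonly enriched annotation terms.
#'
#' @param common output of [common_terms()] (or a character vector of terms).
#' @param annotation an [annotation_table()].
#' @param deg_union gene set to intersect with (typically the DEG union).
#' @return sorted character vector of gene symbols.
#' @export
genes_from_common_terms <- function(common, annotation, deg_union) {
  terms <- if (is.list(common)) unlist(common, use.names = FALSE) else common
  if (!length(terms)) return(character(0))
  hit <- annotation$term %in% terms
  annotated <- unlist(annotation$genes[hit], use.names = FALSE)
  sort_c(intersect(annotated, deg_union))
}
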