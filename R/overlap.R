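# Multi-cohort overlap: disease x tissue groups, Venn partition, and the
# k-of-n shared-gene rule (genes differentially expressed in >= k groups).

#' Merge DEG tables into a disease/tissue group gene set
#'
#' Union of significant gene symbols (direction != not_significant) over the
#' contributing studies of one group.
#'
#' @param tables list of `DEGTable` objects.
#' @param group_id group label, e.g. `"A-PBMC"`.
#' @return a `GeneSetGroup` (list with `group_id`, `genes`, `source_studies`).
#' @export
merge_group <- function(tables, group_id = "group") {
  if (!length(tables)) stop_config("merge_group needs at least one DEGTable")
  genes <- sort_c(unlist(lapply(tables, deg_genes), use.names = FALSE))
  structure(
    list(group_id = group_id, genes = genes,
         source_studies = vapply(tables, function(t) attr(t, "study_id") %||% NA_character_,
                                 character(1))),
    class = "GeneSetGroup"
  )
}

#' Construct a gene-set group directly from a gene vector
#' @param genes character vector of gene symbols (deduplicated).
#' @param group_id group label.
#' @param source_studies optional study ids.
#' @return a `GeneSetGroup`.
#' @export
gene_set_group <- function(genes, group_id, source_studies = character(0)) {
  structure(list(group_id = group_id, genes = sort_c(genes),
                 source_studies = source_studies),
            class = "GeneSetGroup")
}

group_ids <- function(groups) vapply(groups, `[[`, character(1), "group_id")

#' Exclusive Venn partition over gene-set groups
#'
#' Computes all `2^n - 1` exclusive membership regions: a gene lands in the
#' region keyed by exactly the set of groups that contain it.
#'
#' @param groups list of 2-6 `GeneSetGroup` objects with distinct ids.
#' @return a `VennPartition`: list with `regions` (named list of gene
#'   vectors; names are group ids joined by `"&"`), `n_groups`, `group_ids`.
#' @export
venn_partition <- function(groups) {
  ids <- group_ids(groups)
  if (length(groups) < 2L || length(groups) > 6L)
    stop_config("venn_partition supports 2-6 groups")
  if (anyDuplicated(ids)) stop_config("duplicate group ids")
  universe <- sort_c(unlist(lapply(groups, `[[`, "genes"), use.names = FALSE))
  member <- vapply(groups, function(g) universe %in% g$genes,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1)
  key <- apply(member, 1, function(row) paste(ids[row], collapse = "&"))
  regions <- list()
  n <- length(ids)
  for (m in 1:(2^n - 1)) {
    sel <- ids[bitwAnd(m, 2^(seq_len(n) - 1)) > 0]
    regions[[paste(sel, collapse = "&")]] <- character(0)
  }
  found <- split(universe, key)
  regions[names(found)] <- lapply(found, sort_c)
  structure(list(regions = regions, n_groups = n, group_ids = ids),
            class = "VennPartition")
}

#' Region cardinalities of a Venn partition
#' @param partition a `VennPartition`.
#' @return data frame with columns `region` and `n_genes`.
#' @export
venn_counts <- function(partition) {
  data.frame(region = names(partition$regions),
             n_genes = lengths(partition$regions),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Genes present in at least k of n groups
#'
#' Membership ignores direction: a gene up in one group and down in another
#' still counts toward its group total.
#'
#' @param groups list of `GeneSetGroup` objects.
#' @param k minimum number of containing groups (1 <= k <= n).
#' @return sorted character vector of gene symbols.
#' @export
k_of_n_genes <- function(groups, k) {
  n <- length(groups)
  if (!is.numeric(k) || k < 1 || k > n)
    stop_config(sprintf("k must be in [1, %d]", n))
  tab <- table(unlist(lapply(groups, `[[`, "genes"), use.names = FALSE))
  sort_c(names(tab)[tab >= k])
}

#' @export
print.VennPartition <- function(x, ...) {
  cat(sprintf("VennPartition over %d groups (%s): %d genes in %d regions\n",
              x$n_groups, paste(x$group_ids, collapse = ", "),
              sum(lengths(x$regions)), length(x$regions)))
  invisible(x)
}
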