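#' Expression study container
#'
#' Bundles one cohort's gene-by-sample expression matrix with its two-group
#' design and platform kind. Array-like studies hold log2 intensities,
#' counts-like studies hold nonnegative integer counts.
#'
#' @param matrix numeric matrix, rows = probes/genes, columns = samples;
#'   rownames are probe or gene identifiers, colnames are sample ids.
#' @param group character/factor of length `ncol(matrix)` with values
#'   `"case"` / `"control"`.
#' @param platform_kind `"array"` (Gaussian log2 intensities) or `"counts"`
#'   (negative-binomial integer counts).
#' @param study_id identifier for provenance.
#' @param disease,tissue optional design labels (e.g. disease A/B,
#'   PBMC/Tissue) used for the group classification stage.
#' @param gene_map optional named character vector mapping probe id (rowname)
#'   to gene symbol; defaults to identity (rows already gene symbols).
#' @return an object of class `ExpressionStudy`.
#' @export
expression_study <- function(matrix, group, platform_kind = c("array", "counts"),
                             study_id = "study", disease = NA_character_,
                             tissue = NA_character_, gene_map = NULL) {
  platform_kind <- match.arg(platform_kind)
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop_parse("expression matrix must be a numeric matrix")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop_parse("expression matrix needs rownames (genes) and colnames (samples)")
  group <- as.character(group)
  if (length(group) != ncol(matrix))
    stop_config(sprintf("group has length %d but matrix has %d samples",
                        length(group), ncol(matrix)))
  if (!all(group %in% c("case", "control")))
    stop_config("group labels must be 'case' or 'control'")
  if (sum(group == "case") < 1L || sum(group == "control") < 1L)
    stop_config("both case and control samples are required")
  if (platform_kind == "counts") {
    if (any(matrix < 0) || any(matrix != round(matrix)))
      stop_parse("counts-kind study requires nonnegative integer counts")
  }
  if (is.null(gene_map)) {
    gene_map <- stats::setNames(rownames(matrix), rownames(matrix))
  } else {
    missing <- setdiff(rownames(matrix), names(gene_map))
    if (length(missing))
      stop_config(sprintf("gene_map lacks entries for %d probes (e.g. %s)",
                          length(missing), missing[1]))
    gene_map <- gene_map[rownames(matrix)]
  }
  structure(
    list(matrix = matrix, group = group, platform_kind = platform_kind,
         study_id = study_id, disease = disease, tissue = tissue,
         gene_map = gene_map),
    class = "ExpressionStudy"
  )
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  cat(sprintf("ExpressionStudy '%s' [%s] %d features x %d samples (%d case / %d control)\n",
              x$study_id, x$platform_kind, nrow(x$matrix), ncol(x$matrix),
              sum(x$group == "case"), sum(x$group == "control")))
  invisible(x)
}
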