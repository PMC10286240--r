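# Readers and writers for the pipeline's plain-text formats: expression
# matrix TSV + sample sheet, GMT gene sets, weighted edge TSV / SIF, and
# regulator-target TSV. Parsing is strict: ragged rows, duplicate sample
# ids and non-numeric cells raise errors naming the offending location.

#' Write an expression study to TSV
#'
#' Writes the matrix (first column `gene`, then one column per sample) and a
#' sample sheet (`sample_id`, `group`).
#'
#' @param study an [expression_study()].
#' @param path matrix TSV path.
#' @param sheet_path sample sheet TSV path.
#' @return invisibly, `c(path, sheet_path)`.
#' @export
write_expression <- function(study, path, sheet_path) {
  probes <- rownames(study$matrix)
  genes <- unname(study$gene_map[probes])
  df <- if (identical(probes, genes)) {
    data.frame(gene = probes, study$matrix,
               check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    # multi-probe platforms: keep the probe-to-gene map in the file
    data.frame(probe = probes, gene = genes, study$matrix,
               check.names = FALSE, stringsAsFactors = FALSE)
  }
  write_tsv(df, path)
  write_tsv(data.frame(sample_id = colnames(study$matrix),
                       group = study$group, stringsAsFactors = FALSE),
            sheet_path)
  invisible(c(path, sheet_path))
}

check_rectangular <- function(path, n_fields) {
  lines <- readLines(path)
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(nf != n_fields)
  if (length(bad))
    stop_parse(sprintf("%s: ragged row at line %d (%d fields, expected %d)",
                       basename(path), bad[1], nf[bad[1]], n_fields))
  invisible(TRUE)
}

#' Read an expression study from TSV
#'
#' @param path matrix TSV (column `gene` + one column per sample).
#' @param sample_sheet_path sample sheet TSV (`sample_id`, `group` with
#'   values case/control).
#' @param platform_kind `"array"` or `"counts"`.
#' @param study_id,disease,tissue design metadata.
#' @param gene_map optional probe-to-gene map.
#' @return an [expression_study()].
#' @export
read_expression <- function(path, sample_sheet_path,
                            platform_kind = c("array", "counts"),
                            study_id = basename(path), disease = NA_character_,
                            tissue = NA_character_, gene_map = NULL) {
  platform_kind <- match.arg(platform_kind)
  if (!file.exists(path)) stop_parse(sprintf("missing input file: %s", path))
  if (!file.exists(sample_sheet_path))
    stop_parse(sprintf("missing input file: %s", sample_sheet_path))
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  check_rectangular(path, length(header))
  df <- read_tsv(path)
  has_probe <- identical(names(df)[1:2], c("probe", "gene"))
  if (!has_probe && names(df)[1] != "gene")
    stop_parse(sprintf("%s: first column must be 'gene' (or 'probe'+'gene')", path))
  if (anyDuplicated(names(df)))
    stop_parse(sprintf("%s: duplicate sample id '%s'", path,
                       names(df)[duplicated(names(df))][1]))
  meta <- if (has_probe) 1:2 else 1
  ids <- if (has_probe) df$probe else df$gene
  if (anyDuplicated(ids))
    stop_parse(sprintf("%s: duplicate feature id '%s'", path,
                       ids[duplicated(ids)][1]))
  m <- as.matrix(df[, -meta, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-meta], is.numeric, logical(1)))[1]
    stop_parse(sprintf("%s: non-numeric cells in column '%s'", path,
                       names(df)[-meta][bad]))
  }
  rownames(m) <- ids
  if (has_probe && is.null(gene_map))
    gene_map <- stats::setNames(df$gene, df$probe)
  sheet <- read_tsv(sample_sheet_path)
  if (!all(c("sample_id", "group") %in% names(sheet)))
    stop_parse(sprintf("%s: sample sheet needs sample_id and group columns",
                       sample_sheet_path))
  if (anyDuplicated(sheet$sample_id))
    stop_parse(sprintf("%s: duplicate sample id '%s'", sample_sheet_path,
                       sheet$sample_id[duplicated(sheet$sample_id)][1]))
  missing <- setdiff(colnames(m), sheet$sample_id)
  if (length(missing))
    stop_parse(sprintf("%s: samples absent from sheet (e.g. %s)",
                       sample_sheet_path, missing[1]))
  grp <- sheet$group[match(colnames(m), sheet$sample_id)]
  expression_study(m, grp, platform_kind, study_id = study_id,
                   disease = disease, tissue = tissue, gene_map = gene_map)
}

#' Write an annotation table as GMT
#'
#' Standard 3+-column tab format: term, description, member genes. The
#' namespace is carried as a `"NS|term"` prefix in the term field.
#'
#' @param annotation an [annotation_table()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_gmt <- function(annotation, path) {
  ns_map <- c(BP = "BP", CC = "CC", MF = "MF", pathway = "KEGG")
  lines <- vapply(seq_len(nrow(annotation)), function(i) {
    paste(c(paste0(ns_map[[annotation$namespace[i]]], "|", annotation$term[i]),
            if (nzchar(annotation$description[i])) annotation$description[i] else "na",
            annotation$genes[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' @param path GMT path; term fields may carry a `"BP|"` / `"CC|"` / `"MF|"`
#'   / `"KEGG|"` namespace prefix (unprefixed terms default to `pathway`).
#' @return an [annotation_table()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("missing input file: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(annotation_table(character(0), character(0), list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop_parse(sprintf("%s: line %d has fewer than 3 fields", basename(path), short[1]))
  raw <- vapply(parts, `[[`, character(1), 1L)
  ns <- rep("pathway", length(raw))
  term <- raw
  has <- grepl("^(BP|CC|MF|KEGG)\\|", raw)
  ns[has] <- sub("\\|.*$", "", raw[has])
  ns[ns == "KEGG"] <- "pathway"
  term[has] <- sub("^[^|]*\\|", "", raw[has])
  annotation_table(term, ns,
                   lapply(parts, function(p) p[-(1:2)]),
                   description = vapply(parts, `[[`, character(1), 2L))
}

#' Write network edges as 3-column TSV
#' @param net an `InteractionNetwork` or an edge data frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_edges <- function(net, path) {
  edges <- if (inherits(net, "InteractionNetwork")) net$edges else net
  write_tsv(data.frame(source = edges$from, target = edges$to,
                       score = edges$score, stringsAsFactors = FALSE), path)
  invisible(path)
}

#' Read a weighted edge table (TSV or SIF)
#'
#' TSV: columns source/target/score. SIF: whitespace-separated
#' `node1 interaction node2` with scores in an optional 4th sidecar column
#' (missing scores default to 1). Malformed rows are reported with their
#' line numbers.
#'
#' @param path input path; format from the extension (`.sif` vs TSV).
#' @return data frame from/to/score.
#' @export
read_edges <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("missing input file: %s", path))
  if (grepl("\\.sif$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[ \t]+")
    bad <- which(!lengths(parts) %in% c(3L, 4L))
    if (length(bad))
      stop_parse(sprintf("%s: malformed SIF row at line %d", basename(path), bad[1]))
    sc <- vapply(parts, function(p) if (length(p) == 4L) suppressWarnings(as.numeric(p[4])) else 1,
                 numeric(1))
    if (anyNA(sc)) {
      stop_parse(sprintf("%s: non-numeric score at line %d", basename(path),
                         which(is.na(sc))[1]))
    }
    return(data.frame(from = vapply(parts, `[[`, character(1), 1L),
                      to = vapply(parts, `[[`, character(1), 3L),
                      score = sc, stringsAsFactors = FALSE))
  }
  check_rectangular(path, 3L)
  df <- read_tsv(path)
  df <- normalize_edge_frame(df)
  if (anyNA(df$score))
    stop_parse(sprintf("%s: non-numeric score at line %d", basename(path),
                       which(is.na(df$score))[1] + 1L))
  df
}

#' Write a regulator-target table as TSV
#' @param table a `RegulatorTargetTable`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_regulators <- function(table, path) {
  write_tsv(as.data.frame(table, stringsAsFactors = FALSE), path)
  invisible(path)
}

#' Read a regulator-target table from TSV
#' @param path TSV with columns regulator, kind, target, score.
#' @return a `RegulatorTargetTable`.
#' @export
read_regulators <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("missing input file: %s", path))
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  check_rectangular(path, length(header))
  df <- read_tsv(path)
  need <- c("regulator", "target")
  if (!all(need %in% names(df)))
    stop_parse(sprintf("%s: regulator table needs columns regulator, target", path))
  as_regulator_table(df)
}

#' Write a DEG table as TSV
#' @param table a `DEGTable`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_deg_table <- function(table, path) {
  write_tsv(as.data.frame(table, stringsAsFactors = FALSE), path)
  invisible(path)
}
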