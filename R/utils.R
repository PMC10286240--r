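# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
ch_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "crosshub_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

stop_config <- function(msg, ...) ch_stop(msg, "crosshub_config_error", ...)
stop_parse  <- function(msg, ...) ch_stop(msg, "crosshub_parse_error", ...)
stop_stage  <- function(msg, ...) ch_stop(msg, "crosshub_stage_error", ...)

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop_config(msg)
  invisible(TRUE)
}

# Evaluate expr under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic ranking order: score descending, ties lexicographic ascending.
order_by_score <- function(scores) {
  nm <- names(scores)
  order(-scores, nm, method = "radix")
}

# lexicographically sorted character vector (C locale, reproducible)
sort_c <- function(x) sort(unique(as.character(x)), method = "radix")

gene_ids <- function(n, prefix = "G") sprintf("%s%06d", prefix, seq_len(n))

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

md5_of_object <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"), tf)
  unname(tools::md5sum(tf))
}
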