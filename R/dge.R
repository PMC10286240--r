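# Differential expression: moderated t for array-like log2 intensities and a
# negative-binomial Wald test for RNA-seq-like counts, both reporting
# BH-adjusted p-values and the up/down/not_significant call at the standard
# thresholds (adj p < 0.05, |log2FC| >= 1).

DEG_ADJP_CUT <- 0.05
DEG_LFC_CUT <- 1.0

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment with enforced monotonicity, capped at 1 and
#' order-preserving with respect to input positions.
#'
#' @param p_values numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop_config("p-values must lie in [0, 1] with no NA")
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(n / (n:1) * p[o]))
  adj[order(o)]
}

#' Classify differential-expression direction
#'
#' A gene is `up` iff adj p < `adj_p_cut` and log2FC >= `lfc_cut`, `down` iff
#' adj p < `adj_p_cut` and log2FC <= -`lfc_cut`, otherwise `not_significant`.
#'
#' @param log_fc,adj_p numeric vectors (recycled to common length).
#' @param adj_p_cut,lfc_cut thresholds (defaults 0.05 and 1).
#' @return character vector of calls.
#' @export
classify_direction <- function(log_fc, adj_p, adj_p_cut = DEG_ADJP_CUT,
                               lfc_cut = DEG_LFC_CUT) {
  sig <- !is.na(adj_p) & adj_p < adj_p_cut
  out <- rep("not_significant", length(log_fc))
  out[sig & log_fc >= lfc_cut] <- "up"
  out[sig & log_fc <= -lfc_cut] <- "down"
  out
}

new_deg_table <- function(records, study_id, adj_p_cut = DEG_ADJP_CUT,
                          lfc_cut = DEG_LFC_CUT) {
  stopifnot(all(c("gene", "probe", "log_fc", "p_value", "adj_p", "direction")
                %in% names(records)))
  rownames(records) <- NULL
  structure(records,
            study_id = study_id,
            thresholds = c(adj_p_cut = adj_p_cut, lfc_cut = lfc_cut),
            class = c("DEGTable", "data.frame"))
}

#' @export
print.DEGTable <- function(x, ...) {
  s <- deg_summary(x)
  cat(sprintf("DEGTable '%s': %d genes, %d up / %d down (adj p < %g, |log2FC| >= %g)\n",
              attr(x, "study_id"), nrow(x), s[["n_up"]], s[["n_down"]],
              attr(x, "thresholds")[["adj_p_cut"]],
              attr(x, "thresholds")[["lfc_cut"]]))
  NextMethod()
}

# Method-of-moments fit of the scaled inverse-chi-square prior for gene
# variances: s^2 ~ s0^2 * F(df, d0). Works on z = log(s^2); solves
# trigamma(d0/2) = var(z) - trigamma(df/2).
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) {
    s0 <- if (any(ok)) stats::median(s2[ok]) else 1
    return(list(d0 = Inf, s0sq = s0))
  }
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(z) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0sq <- exp(mean(e))
  }
  list(d0 = d0, s0sq = s0sq)
}

# Newton solve of trigamma(x) = y for x > 0.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Moderated-t differential expression for array-like studies
#'
#' Empirical-Bayes moderated t-test for two-group log2-intensity data.
#' Per-gene pooled residual variances are shrunk toward a prior variance
#' `s0^2` with prior degrees of freedom `d0`, both estimated by the method of
#' moments from the distribution of log sample variances; two-sided p-values
#' come from the t distribution with `df_residual + d0` degrees of freedom
#' and are BH-adjusted.
#'
#' @param study an [expression_study()] of kind `"array"`.
#' @param collapse collapse duplicate probes to one record per gene
#'   (see [collapse_duplicates()]); default `TRUE`.
#' @param prior_df,prior_var optional overrides of the estimated `d0` and
#'   `s0^2` (forcing `prior_df = 0` recovers the ordinary pooled t-test).
#' @param adj_p_cut,lfc_cut significance thresholds recorded in the table.
#' @return a `DEGTable` (data frame with columns gene, probe, log_fc,
#'   p_value, adj_p, direction).
#' @export
moderated_t_dge <- function(study, collapse = TRUE, prior_df = NULL,
                            prior_var = NULL, adj_p_cut = DEG_ADJP_CUT,
                            lfc_cut = DEG_LFC_CUT) {
  if (!inherits(study, "ExpressionStudy") || study$platform_kind != "array")
    stop_config("moderated_t_dge expects an array-kind ExpressionStudy")
  x <- study$matrix
  case <- study$group == "case"
  n1 <- sum(case); n2 <- sum(!case)
  if (n1 < 2L || n2 < 2L)
    stop_config("moderated_t_dge needs at least 2 samples per group")
  m1 <- rowMeans(x[, case, drop = FALSE])
  m2 <- rowMeans(x[, !case, drop = FALSE])
  lfc <- m1 - m2
  df <- n1 + n2 - 2
  rss <- rowSums((x[, case, drop = FALSE] - m1)^2) +
    rowSums((x[, !case, drop = FALSE] - m2)^2)
  s2 <- rss / df
  if (all(s2 == 0))
    stop_config("degenerate input: zero residual variance for every gene")
  prior <- fit_variance_prior(s2, df)
  d0 <- prior_df %||% prior$d0
  s0sq <- prior_var %||% prior$s0sq
  if (is.finite(d0) && d0 > 0) {
    s2_post <- (d0 * s0sq + df * s2) / (d0 + df)
    df_tot <- df + d0
  } else if (is.infinite(d0)) {
    s2_post <- rep(s0sq, length(s2))
    df_tot <- Inf
  } else { # d0 == 0: ordinary pooled t
    s2_post <- s2
    df_tot <- df
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  p <- 2 * stats::pt(-abs(tstat), df = df_tot)
  adj <- bh_adjust(p)
  rec <- data.frame(
    gene = unname(study$gene_map[rownames(x)]),
    probe = rownames(x),
    log_fc = unname(lfc),
    p_value = unname(p),
    adj_p = unname(adj),
    direction = classify_direction(lfc, adj, adj_p_cut, lfc_cut),
    stringsAsFactors = FALSE
  )
  tab <- new_deg_table(rec, study$study_id, adj_p_cut, lfc_cut)
  if (collapse) collapse_duplicates(tab, study_id = study$study_id,
                                    adj_p_cut = adj_p_cut, lfc_cut = lfc_cut)
  else tab
}

# Median-of-ratios size factors against the geometric-mean pseudo-reference;
# rows containing any zero are excluded from the reference.
estimate_size_factors <- function(counts) {
  pos <- rowSums(counts == 0) == 0L
  if (!any(pos))
    stop_config("size factors undefined: every gene has at least one zero count")
  loggeo <- rowMeans(log(counts[pos, , drop = FALSE]))
  apply(counts[pos, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - loggeo))
  })
}

# Two-group NB GLM with log link and fixed dispersion alpha, offsets
# log(size factors). Returns beta1 (natural-log fold change) and its
# Wald standard error from the Fisher information.
nb_wald_fit <- function(y, case, sf, alpha, max_iter = 50L, tol = 1e-8) {
  X <- cbind(1, as.numeric(case))
  off <- log(sf)
  # moment start
  mu0 <- pmax(mean(y / sf), 1e-8)
  beta <- c(log(mu0), 0)
  for (it in seq_len(max_iter)) {
    eta <- off + X %*% beta
    mu <- pmax(exp(eta), 1e-10)
    w <- as.vector(mu / (1 + alpha * mu))
    z <- eta - off + (y - mu) / mu
    XtW <- t(X * w)
    fisher <- XtW %*% X
    upd <- tryCatch(solve(fisher, XtW %*% z), error = function(e) NULL)
    if (is.null(upd)) break
    delta <- as.vector(upd) - beta
    beta <- as.vector(upd)
    if (max(abs(delta)) < tol) break
  }
  eta <- off + X %*% beta
  mu <- pmax(exp(eta), 1e-10)
  w <- as.vector(mu / (1 + alpha * mu))
  fisher <- t(X * w) %*% X
  cov <- tryCatch(solve(fisher), error = function(e) matrix(NA_real_, 2, 2))
  list(beta1 = beta[2], se1 = sqrt(cov[2, 2]))
}

#' Negative-binomial Wald differential expression for counts studies
#'
#' Per-sample size factors by median-of-ratios normalisation, per-gene
#' dispersion by the method of moments on normalised counts (floored at
#' 1e-8), and a Wald test of the group coefficient in a two-level NB GLM
#' with log link; BH adjustment. All-zero genes are reported with p = 1
#' rather than dropped.
#'
#' @param study an [expression_study()] of kind `"counts"`.
#' @param adj_p_cut,lfc_cut significance thresholds.
#' @return a `DEGTable`.
#' @export
negbin_wald_dge <- function(study, adj_p_cut = DEG_ADJP_CUT,
                            lfc_cut = DEG_LFC_CUT) {
  if (!inherits(study, "ExpressionStudy") || study$platform_kind != "counts")
    stop_config("negbin_wald_dge expects a counts-kind ExpressionStudy")
  counts <- study$matrix
  case <- study$group == "case"
  sf <- estimate_size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  m <- rowMeans(norm)
  v <- apply(norm, 1, stats::var)
  # Var(K/s) ~ mu * mean(1/s) + alpha * mu^2  (method of moments)
  alpha <- pmax((v - m * mean(1 / sf)) / m^2, 1e-8)
  alpha[!is.finite(alpha)] <- 1e-8
  G <- nrow(counts)
  log_fc <- numeric(G); p <- rep(1, G)
  nonzero <- rowSums(counts) > 0
  for (g in which(nonzero)) {
    fit <- nb_wald_fit(counts[g, ], case, sf, alpha[g])
    log_fc[g] <- fit$beta1 / log(2)
    if (is.finite(fit$se1) && fit$se1 > 0) {
      p[g] <- 2 * stats::pnorm(-abs(fit$beta1 / fit$se1))
    }
  }
  adj <- bh_adjust(p)
  rec <- data.frame(
    gene = unname(study$gene_map[rownames(counts)]),
    probe = rownames(counts),
    log_fc = log_fc,
    p_value = p,
    adj_p = adj,
    direction = classify_direction(log_fc, adj, adj_p_cut, lfc_cut),
    stringsAsFactors = FALSE
  )
  collapse_duplicates(new_deg_table(rec, study$study_id, adj_p_cut, lfc_cut),
                      study_id = study$study_id, adj_p_cut = adj_p_cut,
                      lfc_cut = lfc_cut)
}

#' Collapse duplicate probes to one record per gene
#'
#' Keeps, per gene symbol, the record with maximum |log2FC|; ties are broken
#' by smaller adjusted p, then lexicographically smaller probe id.
#'
#' @param records a `DEGTable` or data frame with columns gene, probe,
#'   log_fc, p_value, adj_p, direction.
#' @param study_id,adj_p_cut,lfc_cut provenance for the returned table.
#' @return a `DEGTable` with one row per gene, ordered by gene symbol.
#' @export
collapse_duplicates <- function(records, study_id = attr(records, "study_id") %||% "study",
                                adj_p_cut = DEG_ADJP_CUT, lfc_cut = DEG_LFC_CUT) {
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    return(new_deg_table(df, study_id, adj_p_cut, lfc_cut))
  o <- order(df$gene, -abs(df$log_fc), df$adj_p, df$probe, method = "radix")
  df <- df[o, , drop = FALSE]
  df <- df[!duplicated(df$gene), , drop = FALSE]
  new_deg_table(df, study_id, adj_p_cut, lfc_cut)
}

#' Count up/down-regulated genes in a DEG table
#'
#' @param table a `DEGTable`.
#' @return named numeric vector `c(n_up, n_down, n_total)`; `n_total` counts
#'   significant genes (up + down).
#' @export
deg_summary <- function(table) {
  c(n_up = sum(table$direction == "up"),
    n_down = sum(table$direction == "down"),
    n_total = sum(table$direction != "not_significant"))
}

#' Significant genes of a DEG table
#' @param table a `DEGTable`.
#' @return character vector of gene symbols with direction != not_significant.
#' @export
deg_genes <- function(table) {
  sort_c(table$gene[table$direction != "not_significant"])
}
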