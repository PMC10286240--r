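# Synthetic-data generators with planted ground truth. These emulate the
# statistical structure the pipeline assumes — two diseases x two tissue
# contexts, array-like log2 intensities or NB counts, a PPI with planted hub
# cliques, GMT annotations with injected enriched terms and regulator tables
# with reliable-score planting — so every downstream stage is testable
# offline. Every generator is deterministic under its seed.

#' Study design for the expression generator
#'
#' @param disease,tissue categorical labels (e.g. `"A"`/`"B"`,
#'   `"PBMC"`/`"Tissue"`).
#' @param platform_kind `"array"` or `"counts"`; determines the noise model.
#' @param n_case,n_control positive sample sizes; the generator enforces the
#'   cohort inclusion rule of at least eight samples in total.
#' @param seed integer RNG seed.
#' @return a `StudyDesign` list.
#' @export
study_design <- function(disease = "A", tissue = "PBMC",
                         platform_kind = c("array", "counts"),
                         n_case = 10L, n_control = 10L, seed = 1L) {
  platform_kind <- match.arg(platform_kind)
  if (n_case < 1L || n_control < 1L) stop_config("sample sizes must be positive")
  if (n_case + n_control < 8L)
    stop_config("study designs require at least eight samples in total")
  structure(list(disease = disease, tissue = tissue,
                 platform_kind = platform_kind,
                 n_case = as.integer(n_case), n_control = as.integer(n_control),
                 seed = as.integer(seed)),
            class = "StudyDesign")
}

#' Simulate one expression study with planted differential expression
#'
#' Array kind: per-gene baseline log2 intensities (Gaussian around 7) with
#' i.i.d. Gaussian noise of standard deviation `dispersion_or_sd`; case
#' means are shifted by `effect_log2fc` on the planted genes. Counts kind:
#' negative-binomial counts with variance `mu + alpha mu^2`
#' (`alpha = dispersion_or_sd`), log-normal baseline means, per-sample size
#' factors drawn log-uniform in \[0.5, 2\] and case means multiplied by
#' `2^effect_log2fc` on the planted genes.
#'
#' @param design a [study_design()].
#' @param genes gene universe (character vector); fixed and shared across
#'   studies of one experiment.
#' @param de_genes planted differentially expressed genes (subset of
#'   `genes`).
#' @param effect_log2fc planted log2 fold change; scalar or one value per
#'   `de_genes` (signed; 0 only if `de_genes` is empty).
#' @param dispersion_or_sd array noise SD (default 0.25) or NB dispersion
#'   alpha (default 0.1).
#' @param study_id identifier.
#' @param duplicate_probes array kind only: emit two probes per gene to
#'   exercise duplicate collapse.
#' @return an [expression_study()].
#' @export
generate_expression_study <- function(design, genes, de_genes = character(0),
                                      effect_log2fc = 2,
                                      dispersion_or_sd = if (design$platform_kind == "array") 0.25 else 0.1,
                                      study_id = "study",
                                      duplicate_probes = FALSE) {
  stopifnot(inherits(design, "StudyDesign"))
  if (dispersion_or_sd <= 0) stop_config("dispersion_or_sd must be positive")
  if (length(setdiff(de_genes, genes)))
    stop_config("de_genes must be a subset of the gene universe")
  if (length(de_genes) && any(effect_log2fc == 0))
    stop_config("effect_log2fc must be nonzero for planted genes")
  effect <- rep_len(effect_log2fc, length(de_genes))
  G <- length(genes)
  n1 <- design$n_case; n2 <- design$n_control
  samples <- c(sprintf("%s_case_%02d", study_id, seq_len(n1)),
               sprintf("%s_ctrl_%02d", study_id, seq_len(n2)))
  grp <- c(rep("case", n1), rep("control", n2))
  shift <- stats::setNames(numeric(G), genes)
  shift[de_genes] <- effect

  with_seed(design$seed, {
    if (design$platform_kind == "array") {
      base <- stats::rnorm(G, mean = 7, sd = 1.5)
      nrep <- if (duplicate_probes) 2L else 1L
      probes <- if (duplicate_probes)
        paste0(rep(genes, each = 2), "_p", rep(1:2, G)) else genes
      gmap <- stats::setNames(rep(genes, each = nrep), probes)
      mu <- matrix(rep(base, each = nrep), nrow = G * nrep, ncol = n1 + n2)
      mu[, seq_len(n1)] <- mu[, seq_len(n1)] + rep(shift, each = nrep)
      x <- mu + matrix(stats::rnorm(length(mu), sd = dispersion_or_sd),
                       nrow = nrow(mu))
      dimnames(x) <- list(probes, samples)
      expression_study(x, grp, "array", study_id = study_id,
                       disease = design$disease, tissue = design$tissue,
                       gene_map = gmap)
    } else {
      base <- exp(stats::rnorm(G, mean = log(200), sd = 1.2))
      sf <- exp(stats::runif(n1 + n2, log(0.5), log(2)))
      mu <- outer(base, sf)
      mu[, seq_len(n1)] <- mu[, seq_len(n1)] * 2^shift
      x <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion_or_sd),
                  nrow = G)
      dimnames(x) <- list(genes, samples)
      expression_study(x, grp, "counts", study_id = study_id,
                       disease = design$disease, tissue = design$tissue)
    }
  })
}

#' Simulate a PPI network with planted hub cliques
#'
#' Each planted hub is the unique shared member of `cliques_per_hub`
#' otherwise-disjoint cliques of `clique_size` vertices; remaining edges are
#' Erdős–Rényi background at `background_edge_prob`. Planted edges carry
#' confidence scores in \[0.7, 1\], background edges uniform \[0.15, 0.9\],
#' so the default 0.40 confidence threshold keeps the planted structure.
#'
#' Defaults mirror a published disease-module interaction network at desk
#' scale: ~200 vertices at background density ~0.012 with 15 planted hubs,
#' comparable to the 12-17 consensus hubs that top-20 centrality lists
#' typically yield.
#'
#' @param n_genes number of vertices (gene ids generated as `P000001`...).
#' @param n_hubs number of planted hubs.
#' @param clique_size clique size (>= 4).
#' @param background_edge_prob Erdős–Rényi edge probability in \[0, 1).
#' @param seed RNG seed.
#' @param cliques_per_hub overlapping cliques per hub (>= 2).
#' @param genes optional vertex names (length `n_genes`).
#' @return list with `network` (an `InteractionNetwork`, threshold 0) and
#'   `truth` (list: `hub_genes`, `clique_members`, `planted_edges`).
#' @export
generate_ppi_with_planted_hubs <- function(n_genes = 200L, n_hubs = 15L,
                                           clique_size = 5L,
                                           background_edge_prob = 0.012,
                                           seed = 1L, cliques_per_hub = 2L,
                                           genes = NULL) {
  if (clique_size < 4L) stop_config("clique_size must be at least 4")
  if (cliques_per_hub < 2L) stop_config("cliques_per_hub must be at least 2")
  if (background_edge_prob < 0 || background_edge_prob >= 1)
    stop_config("background_edge_prob must lie in [0, 1)")
  need <- n_hubs * (1L + cliques_per_hub * (clique_size - 1L))
  if (need > n_genes)
    stop_config(sprintf("infeasible sizes: %d hubs x %d cliques of %d need %d > %d genes",
                        n_hubs, cliques_per_hub, clique_size, need, n_genes))
  genes <- genes %||% gene_ids(n_genes, "P")
  stopifnot(length(genes) == n_genes)
  with_seed(seed, {
    hubs <- if (n_hubs > 0L) sample(genes, n_hubs) else character(0)
    pool <- setdiff(genes, hubs)
    ef <- character(0); et <- character(0)
    members <- character(0)
    for (h in hubs) {
      for (cl in seq_len(cliques_per_hub)) {
        mem <- sample(pool, clique_size - 1L)
        pool <- setdiff(pool, mem)
        members <- c(members, mem)
        cv <- c(h, mem)
        pr <- utils::combn(cv, 2L)
        ef <- c(ef, pr[1, ]); et <- c(et, pr[2, ])
      }
    }
    planted <- data.frame(from = pmin(ef, et), to = pmax(ef, et),
                          stringsAsFactors = FALSE)
    planted <- unique(planted)
    planted$score <- stats::runif(nrow(planted), 0.7, 1)
    # background Erdős–Rényi over all remaining pairs
    idx <- utils::combn(n_genes, 2L)
    a <- genes[idx[1, ]]; b <- genes[idx[2, ]]
    keyp <- paste(planted$from, planted$to, sep = "\r")
    keyall <- paste(pmin(a, b), pmax(a, b), sep = "\r")
    open <- !(keyall %in% keyp)
    pick <- open & stats::runif(length(keyall)) < background_edge_prob
    bg <- data.frame(from = pmin(a, b)[pick], to = pmax(a, b)[pick],
                     stringsAsFactors = FALSE)
    bg$score <- stats::runif(nrow(bg), 0.15, 0.9)
    edges <- rbind(planted, bg)
    net <- build_network(edges, threshold = 0, vertices = genes)
    list(network = net,
         truth = list(hub_genes = sort_c(hubs),
                      clique_members = sort_c(members),
                      planted_edges = planted))
  })
}

#' Simulate a GMT-style annotation table
#'
#' Terms are cycled over the BP/CC/MF namespaces; injected enriched terms
#' keep their gene sets verbatim, decoy terms draw gene sets uniformly from
#' the universe with sizes uniform in `genes_per_term`.
#'
#' @param n_terms number of decoy terms.
#' @param genes gene universe (nonempty).
#' @param genes_per_term integer range `c(min, max)` of decoy set sizes.
#' @param enriched_terms named list term -> gene vector, injected verbatim.
#' @param seed RNG seed.
#' @return an [annotation_table()].
#' @export
generate_annotation <- function(n_terms = 50L, genes,
                                genes_per_term = c(10L, 40L),
                                enriched_terms = list(), seed = 1L) {
  if (!length(genes)) stop_config("empty gene universe")
  ns_cycle <- c("BP", "CC", "MF")
  with_seed(seed, {
    terms <- list()
    if (length(enriched_terms)) {
      for (i in seq_along(enriched_terms)) {
        terms[[names(enriched_terms)[i]]] <- list(
          ns = ns_cycle[(i - 1L) %% 3L + 1L],
          genes = enriched_terms[[i]])
      }
    }
    if (n_terms > 0L) {
      sizes <- sample(genes_per_term[1]:genes_per_term[2], n_terms, replace = TRUE)
      for (j in seq_len(n_terms)) {
        terms[[sprintf("T%04d", j)]] <- list(
          ns = ns_cycle[(j - 1L) %% 3L + 1L],
          genes = sample(genes, min(sizes[j], length(genes))))
      }
    }
    if (!length(terms)) {
      return(annotation_table(character(0), character(0), list()))
    }
    annotation_table(names(terms),
                     vapply(terms, `[[`, character(1), "ns"),
                     lapply(terms, `[[`, "genes"))
  })
}

#' Simulate a regulator-target table with planted hub regulators
#'
#' Planted regulator-target pairs receive reliable scores (> 80); decoy
#' rows draw targets uniformly and scores uniformly in `score_range`.
#'
#' @param n_regulators number of decoy regulators.
#' @param targets target gene pool for decoys.
#' @param planted_hub_regulators named list regulator -> target gene vector,
#'   planted with scores > 80.
#' @param score_range decoy score range (default `c(50, 100)`).
#' @param targets_per_regulator decoy out-degree range.
#' @param kind regulator kind for all rows (default `"miRNA"`).
#' @param seed RNG seed.
#' @return a `RegulatorTargetTable`.
#' @export
generate_regulator_targets <- function(n_regulators = 20L, targets,
                                       planted_hub_regulators = list(),
                                       score_range = c(50, 100),
                                       targets_per_regulator = c(2L, 6L),
                                       kind = "miRNA", seed = 1L) {
  with_seed(seed, {
    reg <- character(0); tgt <- character(0); sc <- numeric(0)
    if (length(planted_hub_regulators)) {
      for (i in seq_along(planted_hub_regulators)) {
        tg <- planted_hub_regulators[[i]]
        reg <- c(reg, rep(names(planted_hub_regulators)[i], length(tg)))
        tgt <- c(tgt, tg)
        sc <- c(sc, stats::runif(length(tg), 80.5, 100))
      }
    }
    if (n_regulators > 0L) {
      ids <- sprintf("%s-dec-%03d", tolower(kind), seq_len(n_regulators))
      degs <- sample(targets_per_regulator[1]:targets_per_regulator[2],
                     n_regulators, replace = TRUE)
      for (j in seq_len(n_regulators)) {
        tg <- sample(targets, min(degs[j], length(targets)))
        reg <- c(reg, rep(ids[j], length(tg)))
        tgt <- c(tgt, tg)
        sc <- c(sc, stats::runif(length(tg), score_range[1], score_range[2]))
      }
    }
    regulator_target_table(reg, tgt, kind = kind,
                           score = if (kind == "miRNA") sc else NA_real_)
  })
}
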