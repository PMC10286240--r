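# End-to-end orchestration: simulate a full input world with planted truth,
# run DE -> overlap -> enrichment -> module networks/hubs -> regulator layers
# -> drug joins from a single config, and serialize a deterministic report.

#' Default pipeline configuration
#'
#' Collects every stage threshold with its standard value: DEG calls at
#' adj p < 0.05 and |log2FC| >= 1; interaction edges kept at the medium
#' confidence 0.40; enrichment significance p < 0.05; miRNA reliability
#' score > 80; top-20 centrality lists with a 3-of-n consensus; shared genes
#' defined by membership in >= 3 groups; hub-regulator consensus over the
#' top 40 nodes; regulator degree filter >= 4 hub targets.
#'
#' @param input_dir directory holding the input files (as written by
#'   [simulate_inputs()]).
#' @param out_dir report output directory.
#' @param seed integer seed recorded in the report.
#' @param ... overrides of any config field.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(input_dir = ".", out_dir = "crosshub-report",
                            seed = 1L, ...) {
  cfg <- list(
    input_dir = input_dir,
    out_dir = out_dir,
    seed = as.integer(seed),
    studies = list(),
    annotation_gmt = file.path(input_dir, "annotation.gmt"),
    ppi_edges = file.path(input_dir, "ppi_edges.tsv"),
    mirna_targets = file.path(input_dir, "mirna_targets.tsv"),
    tf_targets = file.path(input_dir, "tf_targets.tsv"),
    drug_targets = file.path(input_dir, "drug_targets.tsv"),
    adj_p = 0.05, lfc = 1.0, edge = 0.40, enrich_p = 0.05,
    regulator_score = 80, top_k = 20L, top_n_regulators = 40L,
    min_methods = 3L, k_of_n = 3L, min_regulator_targets = 4L,
    hub_methods = c("mcc", "degree", "closeness", "betweenness"),
    regulator_methods = c("degree", "betweenness", "closeness", "stress"),
    skip_stages = character(0)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop_config(sprintf("unknown config field '%s'", unknown[1]))
  cfg[names(dots)] <- dots
  validate_config(cfg)
}

validate_config <- function(cfg) {
  chk <- function(x, lo, hi, nm)
    assert_that(is.numeric(x) && x >= lo && x <= hi,
                sprintf("config field '%s' out of range [%g, %g]", nm, lo, hi))
  chk(cfg$adj_p, 0, 1, "adj_p"); chk(cfg$lfc, 0, Inf, "lfc")
  chk(cfg$edge, 0, 1, "edge"); chk(cfg$enrich_p, 0, 1, "enrich_p")
  chk(cfg$regulator_score, 0, 100, "regulator_score")
  chk(cfg$top_k, 1, Inf, "top_k"); chk(cfg$min_methods, 1, Inf, "min_methods")
  chk(cfg$k_of_n, 1, Inf, "k_of_n")
  for (s in cfg$studies) {
    need <- c("id", "expr", "sheet", "platform", "disease", "tissue", "group")
    miss <- setdiff(need, names(s))
    if (length(miss))
      stop_config(sprintf("study spec missing field '%s'", miss[1]))
  }
  structure(cfg, class = c("PipelineConfig", "list"))
}

#' Read a pipeline config from JSON
#' @param path JSON file with any subset of [pipeline_config()] fields.
#' @param ... overrides applied after the file.
#' @return a `PipelineConfig`.
#' @export
read_config <- function(path, ...) {
  if (!file.exists(path)) stop_config(sprintf("missing config file: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  base_args <- raw[intersect(names(raw), c("input_dir", "out_dir", "seed"))]
  cfg <- do.call(pipeline_config, base_args)
  rest <- setdiff(names(raw), c("input_dir", "out_dir", "seed"))
  cfg[rest] <- raw[rest]
  dots <- list(...)
  cfg[names(dots)] <- dots
  validate_config(cfg)
}

#' Simulate a complete input world with planted truth
#'
#' Builds a two-disease x two-tissue experiment at desk scale and writes
#' every pipeline input to `dir`: five expression studies (three array-like
#' for disease A — one with duplicate probes — and two counts-like for
#' disease B), a PPI with planted hub cliques over the shared genes, a GMT
#' annotation with terms enriched in both diseases, and miRNA / TF / drug
#' regulator tables with planted hub regulators. Returns (and writes as
#' JSON) the planted truth for recovery tests.
#'
#' @param dir output directory (created).
#' @param seed integer master seed; all study/generator seeds derive from it.
#' @param n_genes gene universe size (default 2000).
#' @param n_shared shared genes planted in >= 3 of the 4 groups
#'   (default 200; these carry the PPI).
#' @param n_specific group-specific DE genes per group (default 120).
#' @param n_case,n_control per-study sample sizes (default 10/10).
#' @param effect_log2fc planted |log2FC| (default 2).
#' @param array_sd,nb_dispersion noise parameters (defaults 0.25, 0.1).
#' @param n_hubs,clique_size,background_edge_prob PPI planting (defaults
#'   15, 5, 0.012).
#' @param n_terms decoy annotation terms (default 60).
#' @param n_planted_terms terms enriched in both diseases (default 5).
#' @return invisibly, a list with `config` (a ready `PipelineConfig`) and
#'   `truth` (planted gene sets and regulators).
#' @export
simulate_inputs <- function(dir, seed = 1L, n_genes = 2000L, n_shared = 200L,
                            n_specific = 120L, n_case = 10L, n_control = 10L,
                            effect_log2fc = 2, array_sd = 0.25,
                            nb_dispersion = 0.1, n_hubs = 15L,
                            clique_size = 5L, background_edge_prob = 0.012,
                            n_terms = 60L, n_planted_terms = 5L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genes <- gene_ids(n_genes)
  groups <- c("A-PBMC", "A-Tissue", "B-PBMC", "B-Tissue")

  plan <- with_seed(seed, {
    shared <- sample(genes, n_shared)
    # half the shared genes sit in all four groups, half in a random three
    four_way <- shared[seq_len(floor(n_shared / 2))]
    three_way <- setdiff(shared, four_way)
    shared_groups <- lapply(seq_along(shared), function(i) {
      if (shared[i] %in% four_way) groups else sample(groups, 3L)
    })
    names(shared_groups) <- shared
    pool <- setdiff(genes, shared)
    specific <- stats::setNames(vector("list", length(groups)), groups)
    for (g in groups) {
      specific[[g]] <- sample(pool, n_specific)
      pool <- setdiff(pool, specific[[g]])
    }
    signs <- stats::setNames(sample(c(-1, 1), n_genes, replace = TRUE), genes)
    list(shared = sort_c(shared), shared_groups = shared_groups,
         specific = specific, signs = signs)
  })
  de_of_group <- lapply(stats::setNames(groups, groups), function(g) {
    sort_c(c(plan$specific[[g]],
             names(plan$shared_groups)[vapply(plan$shared_groups,
                                              function(gs) g %in% gs, logical(1))]))
  })

  study_specs <- list(
    list(id = "A_PBMC_1", group = "A-PBMC", disease = "A", tissue = "PBMC",
         platform = "array", dup = FALSE),
    list(id = "A_PBMC_2", group = "A-PBMC", disease = "A", tissue = "PBMC",
         platform = "array", dup = TRUE),
    list(id = "A_Tissue_1", group = "A-Tissue", disease = "A", tissue = "Tissue",
         platform = "array", dup = FALSE),
    list(id = "B_PBMC_1", group = "B-PBMC", disease = "B", tissue = "PBMC",
         platform = "counts", dup = FALSE),
    list(id = "B_Tissue_1", group = "B-Tissue", disease = "B", tissue = "Tissue",
         platform = "counts", dup = FALSE)
  )
  cfg_studies <- list()
  for (i in seq_along(study_specs)) {
    sp <- study_specs[[i]]
    de <- de_of_group[[sp$group]]
    des <- study_design(disease = sp$disease, tissue = sp$tissue,
                        platform_kind = sp$platform, n_case = n_case,
                        n_control = n_control, seed = seed * 101L + i)
    st <- generate_expression_study(
      des, genes, de_genes = de,
      effect_log2fc = effect_log2fc * plan$signs[de],
      dispersion_or_sd = if (sp$platform == "array") array_sd else nb_dispersion,
      study_id = sp$id, duplicate_probes = sp$dup)
    expr_path <- file.path(dir, paste0(sp$id, "_expr.tsv"))
    sheet_path <- file.path(dir, paste0(sp$id, "_samples.tsv"))
    write_expression(st, expr_path, sheet_path)
    cfg_studies[[i]] <- list(id = sp$id, expr = expr_path, sheet = sheet_path,
                             platform = sp$platform, disease = sp$disease,
                             tissue = sp$tissue, group = sp$group)
  }

  ppi <- generate_ppi_with_planted_hubs(
    n_genes = n_shared, n_hubs = n_hubs, clique_size = clique_size,
    background_edge_prob = background_edge_prob, seed = seed + 7L,
    genes = plan$shared)
  write_edges(ppi$network, file.path(dir, "ppi_edges.tsv"))

  all_de <- sort_c(unlist(de_of_group, use.names = FALSE))
  planted_terms <- with_seed(seed + 11L, {
    out <- list()
    specific_pool <- unlist(plan$specific, use.names = FALSE)
    for (j in seq_len(n_planted_terms)) {
      out[[sprintf("SHARED%02d", j)]] <- c(sample(plan$shared, 25L),
                                           sample(specific_pool, 15L))
    }
    out
  })
  annot <- generate_annotation(n_terms = n_terms, genes = genes,
                               enriched_terms = planted_terms,
                               seed = seed + 13L)
  write_gmt(annot, file.path(dir, "annotation.gmt"))

  planted_regs <- with_seed(seed + 17L, {
    out <- list()
    for (j in seq_len(5L)) {
      out[[sprintf("mir-planted-%02d", j)]] <-
        sample(ppi$truth$hub_genes, min(5L, length(ppi$truth$hub_genes)))
    }
    out
  })
  mirna <- generate_regulator_targets(
    n_regulators = 60L, targets = all_de,
    planted_hub_regulators = planted_regs, kind = "miRNA", seed = seed + 19L)
  write_regulators(mirna, file.path(dir, "mirna_targets.tsv"))
  tf <- generate_regulator_targets(
    n_regulators = 10L, targets = plan$shared,
    planted_hub_regulators = stats::setNames(
      with_seed(seed + 23L, lapply(1:4, function(i)
        sample(ppi$truth$hub_genes, min(6L, length(ppi$truth$hub_genes))))),
      paste0("TF-planted-", 1:4)),
    kind = "TF", seed = seed + 29L)
  write_regulators(tf, file.path(dir, "tf_targets.tsv"))
  drugs <- generate_regulator_targets(
    n_regulators = 20L, targets = plan$shared, kind = "drug", seed = seed + 31L)
  write_regulators(drugs, file.path(dir, "drug_targets.tsv"))

  cfg <- pipeline_config(input_dir = dir, out_dir = file.path(dir, "report"),
                         seed = seed, studies = cfg_studies)
  truth <- list(
    shared_genes = plan$shared,
    de_genes_by_group = de_of_group,
    hub_genes = ppi$truth$hub_genes,
    planted_terms = names(planted_terms),
    planted_regulators = names(planted_regs)
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = FALSE)
  jsonlite::write_json(cfg[c("input_dir", "out_dir", "seed", "studies")],
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(config = cfg, truth = truth))
}

run_stage <- function(name, quiet, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    if (inherits(e, "crosshub_error")) {
      e$message <- sprintf("stage '%s': %s", name, conditionMessage(e))
      stop(e)
    }
    stop_stage(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
  })
  if (!quiet)
    message(sprintf("[crosshub] %-12s %.2fs", name,
                    proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full crosstalk pipeline
#'
#' Executes, in order: per-study differential expression; group merge, Venn
#' partition and k-of-n shared genes (module 1); per-disease enrichment,
#' common terms and the common-term gene set (module 2); PPI construction
#' and consensus hub detection for both modules; miRNA/TF regulator layers
#' and the drug-gene join; report serialization.
#'
#' @param config a `PipelineConfig` from [pipeline_config()] /
#'   [read_config()].
#' @param quiet suppress stage timing messages.
#' @return a `ReportBundle` (invisibly written to `config$out_dir` with a
#'   content-hash manifest).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- validate_config(config)
  if (!length(config$studies)) stop_config("config lists no studies")
  bundle <- list(config = config)

  deg_tables <- if ("dge" %in% config$skip_stages) {
    # consume cached per-study DEG tables from a previous run's out_dir
    run_stage("dge(cached)", quiet, {
      lapply(config$studies, function(s) {
        p <- file.path(config$out_dir, sprintf("deg_%s.tsv", s$id))
        if (!file.exists(p))
          stop_stage(sprintf("dge skipped but cached table missing: %s", p))
        new_deg_table(read_tsv(p), s$id, config$adj_p, config$lfc)
      })
    })
  } else run_stage("dge", quiet, {
    lapply(config$studies, function(s) {
      st <- read_expression(s$expr, s$sheet, platform_kind = s$platform,
                            study_id = s$id, disease = s$disease,
                            tissue = s$tissue)
      if (s$platform == "array")
        moderated_t_dge(st, adj_p_cut = config$adj_p, lfc_cut = config$lfc)
      else
        negbin_wald_dge(st, adj_p_cut = config$adj_p, lfc_cut = config$lfc)
    })
  })
  names(deg_tables) <- vapply(config$studies, `[[`, character(1), "id")
  bundle$deg_tables <- deg_tables
  bundle$deg_summary <- data.frame(
    study = names(deg_tables),
    group = vapply(config$studies, `[[`, character(1), "group"),
    t(vapply(deg_tables, deg_summary, numeric(3))),
    row.names = NULL, stringsAsFactors = FALSE)

  overlap <- run_stage("overlap", quiet, {
    glabels <- vapply(config$studies, `[[`, character(1), "group")
    groups <- lapply(sort_c(glabels), function(g) {
      merge_group(deg_tables[glabels == g], group_id = g)
    })
    part <- venn_partition(groups)
    module1 <- k_of_n_genes(groups, config$k_of_n)
    list(groups = groups, partition = part, module1 = module1)
  })
  bundle$groups <- overlap$groups
  bundle$venn <- overlap$partition
  bundle$module1_genes <- overlap$module1

  enr <- run_stage("enrichment", quiet, {
    annot <- read_gmt(config$annotation_gmt)
    diseases <- vapply(config$studies, `[[`, character(1), "disease")
    ids <- names(deg_tables)
    background <- sort_c(unlist(lapply(deg_tables, function(t) t$gene),
                                use.names = FALSE))
    per_disease <- lapply(sort_c(diseases), function(d) {
      dg <- sort_c(unlist(lapply(deg_tables[diseases == d], deg_genes),
                          use.names = FALSE))
      enrich_gene_set(dg, annot, background = background,
                      alpha = config$enrich_p)
    })
    names(per_disease) <- sort_c(diseases)
    if (length(per_disease) != 2L)
      stop_stage("enrichment stage expects exactly two diseases")
    common <- common_terms(per_disease[[1]], per_disease[[2]],
                           alpha = config$enrich_p)
    deg_union <- sort_c(unlist(lapply(deg_tables, deg_genes), use.names = FALSE))
    module2 <- genes_from_common_terms(common, annot, deg_union)
    list(annotation = annot, per_disease = per_disease, common = common,
         module2 = module2, deg_union = deg_union)
  })
  bundle$enrichment <- enr$per_disease
  bundle$common_terms <- enr$common
  bundle$module2_genes <- enr$module2

  hubs <- run_stage("hubs", quiet, {
    ppi <- build_network(read_edges(config$ppi_edges), threshold = config$edge)
    mod_hub <- function(genes) {
      sub <- induce_subnetwork(ppi, genes)
      rk <- centrality_rankings(sub, config$hub_methods)
      list(network = sub, rankings = rk,
           consensus = consensus_hubs(rk, top_k = config$top_k,
                                      min_methods = config$min_methods))
    }
    m1 <- mod_hub(bundle$module1_genes)
    m2 <- mod_hub(bundle$module2_genes)
    list(ppi = ppi, module1 = m1, module2 = m2,
         union_hubs = sort_c(union(m1$consensus$hubs, m2$consensus$hubs)))
  })
  bundle$ppi <- hubs$ppi
  bundle$module1 <- hubs$module1
  bundle$module2 <- hubs$module2
  bundle$union_hubs <- hubs$union_hubs

  reg <- run_stage("regulatory", quiet, {
    mirna <- filter_reliable_targets(read_regulators(config$mirna_targets),
                                     min_score = config$regulator_score)
    mir_net <- hub_regulator_network(mirna, bundle$union_hubs, kind = "miRNA")
    mir_keep <- regulators_by_min_targets(mir_net,
                                          config$min_regulator_targets)
    mir_cons <- consensus_hub_regulators(mir_net,
                                         methods = config$regulator_methods,
                                         top_n = config$top_n_regulators,
                                         min_methods = config$min_methods)
    tf_net <- hub_regulator_network(read_regulators(config$tf_targets),
                                    bundle$union_hubs, kind = "TF")
    drug_net <- drug_gene_join(read_regulators(config$drug_targets),
                               bundle$union_hubs)
    list(mirna_network = mir_net, mirna_filtered = mir_keep,
         mirna_consensus = mir_cons,
         mirna_summary = regulator_summary(mir_net, mir_cons),
         tf_network = tf_net, tf_summary = regulator_summary(tf_net),
         drug_network = drug_net)
  })
  bundle$regulatory <- reg

  bundle <- structure(bundle, class = "ReportBundle")
  run_stage("report", quiet, write_report(bundle, config$out_dir))
  invisible(bundle)
}

#' @export
print.ReportBundle <- function(x, ...) {
  cat("crosshub ReportBundle\n")
  cat(sprintf("  module 1: %d genes -> %d hubs\n", length(x$module1_genes),
              length(x$module1$consensus$hubs)))
  cat(sprintf("  module 2: %d genes -> %d hubs\n", length(x$module2_genes),
              length(x$module2$consensus$hubs)))
  cat(sprintf("  union hubs: %d\n", length(x$union_hubs)))
  invisible(x)
}

#' Serialize a report bundle
#'
#' Writes per-study DEG tables, the DEG summary, Venn region table and
#' counts, module gene lists, per-method rankings, consensus hub tables
#' with support counts, enrichment tables, regulator summaries, drug edges,
#' a JSON summary and a manifest listing every artifact with its md5
#' content hash. Deterministic: identical bundles produce identical
#' manifests.
#'
#' @param bundle a `ReportBundle`.
#' @param dir output directory (created).
#' @return invisibly, the manifest data frame (file, md5, bytes).
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(rel, writer) {
    p <- file.path(dir, rel)
    writer(p)
    paths <<- c(paths, p)
  }
  for (id in names(bundle$deg_tables))
    put(sprintf("deg_%s.tsv", id),
        function(p) write_deg_table(bundle$deg_tables[[id]], p))
  put("deg_summary.tsv", function(p) write_tsv(bundle$deg_summary, p))
  put("venn_counts.tsv", function(p) write_tsv(venn_counts(bundle$venn), p))
  put("venn_regions.tsv", function(p) {
    rg <- bundle$venn$regions
    write_tsv(data.frame(region = rep(names(rg), lengths(rg)),
                         gene = unlist(rg, use.names = FALSE),
                         stringsAsFactors = FALSE), p)
  })
  put("module1_genes.txt", function(p) writeLines(bundle$module1_genes, p))
  put("module2_genes.txt", function(p) writeLines(bundle$module2_genes, p))
  for (mod in c("module1", "module2")) {
    cons <- bundle[[mod]]$consensus
    for (m in names(bundle[[mod]]$rankings)) {
      rk <- bundle[[mod]]$rankings[[m]]
      put(sprintf("%s_ranking_%s.tsv", mod, m), function(p) {
        write_tsv(data.frame(gene = rk$order,
                             score = unname(rk$scores[rk$order]),
                             stringsAsFactors = FALSE), p)
      })
    }
    put(sprintf("%s_hubs.tsv", mod), function(p) {
      sup <- cons$support[cons$hubs]
      write_tsv(data.frame(gene = cons$hubs, support = as.integer(sup),
                           stringsAsFactors = FALSE), p)
    })
  }
  put("union_hubs.txt", function(p) writeLines(bundle$union_hubs, p))
  for (d in names(bundle$enrichment))
    put(sprintf("enrichment_%s.tsv", d),
        function(p) write_tsv(bundle$enrichment[[d]], p))
  put("common_terms.tsv", function(p) {
    ct <- bundle$common_terms
    write_tsv(data.frame(namespace = rep(names(ct), lengths(ct)),
                         term = unlist(ct, use.names = FALSE),
                         stringsAsFactors = FALSE), p)
  })
  put("mirna_summary.tsv", function(p) write_tsv(bundle$regulatory$mirna_summary, p))
  put("mirna_edges.tsv", function(p) write_tsv(bundle$regulatory$mirna_network$edges, p))
  put("tf_summary.tsv", function(p) write_tsv(bundle$regulatory$tf_summary, p))
  put("drug_edges.tsv", function(p) write_tsv(bundle$regulatory$drug_network$edges, p))

  cfg <- bundle$config
  summary_json <- list(
    seed = cfg$seed,
    config_hash = md5_of_object(cfg[setdiff(names(cfg), c("input_dir", "out_dir"))]),
    thresholds = cfg[c("adj_p", "lfc", "edge", "enrich_p", "regulator_score",
                       "top_k", "top_n_regulators", "min_methods", "k_of_n",
                       "min_regulator_targets")],
    deg_summary = bundle$deg_summary,
    venn_counts = venn_counts(bundle$venn),
    n_module1_genes = length(bundle$module1_genes),
    n_module2_genes = length(bundle$module2_genes),
    module1_hubs = bundle$module1$consensus$hubs,
    module2_hubs = bundle$module2$consensus$hubs,
    union_hubs = bundle$union_hubs,
    n_union_hubs = length(bundle$union_hubs),
    common_term_counts = as.list(attr(bundle$common_terms, "counts")),
    n_mirna_filtered = length(bundle$regulatory$mirna_filtered),
    mirna_consensus = bundle$regulatory$mirna_consensus,
    n_drugs = attr(bundle$regulatory$drug_network, "n_drugs")
  )
  put("report.json", function(p)
    jsonlite::write_json(summary_json, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE))
  manifest <- data.frame(
    file = basename(paths),
    md5 = unname(tools::md5sum(paths)),
    bytes = unname(file.size(paths)),
    stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file, method = "radix"), , drop = FALSE]
  rownames(manifest) <- NULL
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
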