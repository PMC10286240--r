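# Generators: planted structure, determinism, error contracts.

genes200 <- sprintf("G%06d", 1:200)

test_that("array generator plants the requested shift and is seed-deterministic", {
  d <- study_design(n_case = 10, n_control = 10, seed = 42)
  st <- generate_expression_study(d, genes200, de_genes = "G000001",
                                  effect_log2fc = 2, dispersion_or_sd = 0.1)
  # oracle: direct group-mean subtraction on the planted gene
  diff <- mean(st$matrix["G000001", st$group == "case"]) -
    mean(st$matrix["G000001", st$group == "control"])
  expect_lt(abs(diff - 2), 0.15)
  # null genes centred at zero difference
  null_diff <- rowMeans(st$matrix[-1, st$group == "case"]) -
    rowMeans(st$matrix[-1, st$group == "control"])
  expect_lt(max(abs(null_diff)), 0.5)
  st2 <- generate_expression_study(d, genes200, de_genes = "G000001",
                                   effect_log2fc = 2, dispersion_or_sd = 0.1)
  expect_identical(st$matrix, st2$matrix)
})

test_that("null case: no planted genes gives expected logFC 0 everywhere", {
  d <- study_design(n_case = 20, n_control = 20, seed = 7)
  st <- generate_expression_study(d, genes200, de_genes = character(0),
                                  dispersion_or_sd = 0.1)
  diffs <- rowMeans(st$matrix[, st$group == "case"]) -
    rowMeans(st$matrix[, st$group == "control"])
  expect_lt(mean(abs(diffs)), 0.05)
})

test_that("counts generator draws NB counts with planted fold change", {
  d <- study_design(platform_kind = "counts", n_case = 10, n_control = 10,
                    seed = 9)
  st <- generate_expression_study(d, genes200, de_genes = genes200[1:5],
                                  effect_log2fc = 2, dispersion_or_sd = 0.05)
  expect_true(all(st$matrix >= 0))
  expect_true(all(st$matrix == round(st$matrix)))
  expect_identical(st$matrix,
                   generate_expression_study(d, genes200, genes200[1:5],
                                             2, 0.05)$matrix)
})

test_that("expression generator validates its contract", {
  expect_error(study_design(n_case = 3, n_control = 3), "eight")
  expect_error(study_design(n_case = 0, n_control = 10), "positive")
  d <- study_design(seed = 1)
  expect_error(generate_expression_study(d, genes200, de_genes = "NOPE"),
               "universe")
  expect_error(generate_expression_study(d, genes200, de_genes = "G000001",
                                         effect_log2fc = 0),
               "nonzero")
  expect_error(generate_expression_study(d, genes200, dispersion_or_sd = -1),
               "positive")
})

test_that("duplicate-probe studies emit two probes per gene", {
  d <- study_design(n_case = 5, n_control = 5, seed = 2)
  st <- generate_expression_study(d, genes200[1:50], duplicate_probes = TRUE)
  expect_equal(nrow(st$matrix), 100)
  expect_equal(sort(unique(unname(st$gene_map))), sort(genes200[1:50]))
})

test_that("zero background with one hub is exactly two overlapping cliques", {
  g <- generate_ppi_with_planted_hubs(n_genes = 9, n_hubs = 1, clique_size = 4,
                                      background_edge_prob = 0, seed = 5)
  net <- g$network
  expect_equal(nrow(net$edges), 2 * choose(4, 2))
  hub <- g$truth$hub_genes
  expect_length(hub, 1)
  deg <- degree_centrality(net)$scores
  expect_equal(unname(deg[hub]), 6)             # shared member of both cliques
  expect_true(all(net$edges$score >= 0.7))      # planted edges only
  # MCC sees exactly two maximal 4-cliques through the hub
  expect_equal(unname(mcc_centrality(net)$scores[hub]), 2 * factorial(3))
})

test_that("planted hubs dominate MCC at the documented example settings", {
  g <- generate_ppi_with_planted_hubs(n_genes = 200, n_hubs = 5,
                                      clique_size = 5,
                                      background_edge_prob = 0.02, seed = 1)
  top <- top_k(mcc_centrality(g$network), 20)
  expect_true(all(g$truth$hub_genes %in% top))
})

test_that("hub generator honours edge cases and feasibility", {
  g0 <- generate_ppi_with_planted_hubs(n_genes = 30, n_hubs = 0,
                                       clique_size = 4,
                                       background_edge_prob = 0.1, seed = 3)
  expect_length(g0$truth$hub_genes, 0)
  expect_error(generate_ppi_with_planted_hubs(n_genes = 10, n_hubs = 3,
                                              clique_size = 5,
                                              background_edge_prob = 0.1),
               "infeasible")
  g1 <- generate_ppi_with_planted_hubs(seed = 11)
  g2 <- generate_ppi_with_planted_hubs(seed = 11)
  expect_identical(g1$network$edges, g2$network$edges)
  # truth containment invariants
  expect_true(all(g1$truth$hub_genes %in% g1$network$vertices))
  expect_true(all(g1$truth$clique_members %in% g1$network$vertices))
})

test_that("annotation generator injects enriched terms verbatim", {
  planted <- list(MYTERM = genes200[1:30])
  ann <- generate_annotation(n_terms = 40, genes = genes200,
                             enriched_terms = planted, seed = 4)
  expect_equal(sort(ann$genes[[which(ann$term == "MYTERM")]]),
               sort(genes200[1:30]))
  expect_true(all(ann$namespace %in% c("BP", "CC", "MF")))
  # injected term recovered by enrichment when its genes are the query;
  # oracle: PMF summation gives an astronomically small tail
  res <- enrich_gene_set(genes200[1:30], ann, background = genes200)
  expect_equal(res$term[1], "MYTERM")
  expect_lt(res$p[1], 0.01)
  expect_lt(oracle_hyper_tail(200, 30, 30, 30), 1e-10)
  ann2 <- generate_annotation(n_terms = 40, genes = genes200,
                              enriched_terms = planted, seed = 4)
  expect_identical(ann$genes, ann2$genes)
  empty <- generate_annotation(n_terms = 0, genes = genes200, seed = 1)
  expect_equal(nrow(empty), 0)
  expect_error(generate_annotation(n_terms = 5, genes = character(0)),
               "universe")
})

test_that("regulator generator plants reliable high-score hub regulators", {
  planted <- list(`mir-x` = genes200[1:4])
  tab <- generate_regulator_targets(n_regulators = 30, targets = genes200,
                                    planted_hub_regulators = planted, seed = 6)
  kept <- filter_reliable_targets(tab, min_score = 80)
  net <- hub_regulator_network(kept, hubs = genes200[1:4])
  expect_true("mir-x" %in% regulators_by_min_targets(net, min_targets = 4))
  expect_identical(
    tab,
    generate_regulator_targets(30, genes200, planted, seed = 6))
  # empty planting: decoys rarely hit 4 of the 4 "hub" genes
  tab0 <- generate_regulator_targets(n_regulators = 30, targets = genes200,
                                     seed = 8)
  net0 <- hub_regulator_network(filter_reliable_targets(tab0), genes200[1:4])
  expect_length(regulators_by_min_targets(net0, 4), 0)
})
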