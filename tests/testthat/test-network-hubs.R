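# Network construction, neighbor overlap, the five centralities (vs oracles
# and igraph), ranking determinism, and the consensus hub rule.

test_that("build_network thresholds inclusively and dedupes", {
  e <- edge_df(c("a", "b", "c", "d", "e"), c("b", "c", "d", "e", "a"),
               c(.2, .3, .4, .5, .9))
  expect_equal(nrow(build_network(e, 0)$edges), 5)
  expect_equal(nrow(build_network(e, 0.40)$edges), 3)     # boundary inclusive
  expect_equal(nrow(build_network(e, 1.0)$edges), 0)
  # self loops and duplicates
  e2 <- edge_df(c("a", "b", "x"), c("b", "a", "x"), c(.5, .8, .9))
  net2 <- build_network(e2, 0)
  expect_equal(nrow(net2$edges), 1)
  expect_equal(net2$edges$score, 0.8)                     # max kept
  expect_false("x" %in% net2$vertices)                    # self-loop dropped
  net3 <- build_network(e2, 0, vertices = c("x", "z"))
  expect_true(all(c("x", "z") %in% net3$vertices))        # explicit isolates
  expect_error(build_network(edge_df("a", "b", 1.5), 0), "\\[0, 1\\]")
})

test_that("neighbor_overlap_score is the Dice coefficient of neighborhoods", {
  net <- toy_net(c("u", "u", "v", "v"), c("a", "b", "b", "c"))
  expect_equal(neighbor_overlap_score(net, "u", "v"), 0.5)
  tw <- toy_net(c("u", "v"), c("a", "a"))                 # identical nonempty
  expect_equal(neighbor_overlap_score(tw, "u", "v"), 1)
  dj <- toy_net(c("u", "v"), c("a", "b"))                 # disjoint
  expect_equal(neighbor_overlap_score(dj, "u", "v"), 0)
  iso <- build_network(edge_df("a", "b", 1), 0, vertices = c("x", "y"))
  expect_error(neighbor_overlap_score(iso, "x", "y"), "isolated")
  expect_equal(neighbor_overlap_score(net, "u", "v"),
               neighbor_overlap_score(net, "v", "u"))     # symmetric
})

test_that("centralities match hand values on canonical small graphs", {
  p3 <- net_path3()
  expect_equal(unname(closeness_centrality(p3)$scores[c("a", "b", "c")]),
               c(1.5, 2, 1.5))
  expect_equal(unname(betweenness_centrality(p3)$scores[["b"]]), 1)
  expect_equal(unname(stress_centrality(p3)$scores[["b"]]), 1)
  expect_equal(unname(mcc_centrality(p3)$scores[c("a", "b", "c")]), c(1, 2, 1))

  k4 <- net_complete(4)
  expect_true(all(degree_centrality(k4)$scores == 3))
  expect_true(all(betweenness_centrality(k4)$scores == 0))
  expect_true(all(stress_centrality(k4)$scores == 0))
  expect_true(all(closeness_centrality(k4)$scores == 3))
  expect_true(all(mcc_centrality(k4)$scores == factorial(3)))

  st5 <- net_star(5)
  expect_equal(unname(degree_centrality(st5)$scores[["hub"]]), 5)
  expect_equal(unname(betweenness_centrality(st5)$scores[["hub"]]), choose(5, 2))
  expect_equal(unname(mcc_centrality(st5)$scores[["hub"]]), 5)  # degree fallback

  st3 <- net_star(3)
  expect_equal(unname(betweenness_centrality(st3)$scores[["hub"]]), 3)

  tri <- net_complete(3)
  expect_true(all(mcc_centrality(tri)$scores == 2))

  c4 <- toy_net(c("a", "b", "c", "d"), c("b", "c", "d", "a"))
  expect_true(all(stress_centrality(c4)$scores == 1))

  iso <- build_network(edge_df("a", "b", 1), 0, vertices = "z")
  expect_equal(unname(closeness_centrality(iso)$scores[["z"]]), 0)
  expect_equal(unname(mcc_centrality(iso)$scores[["z"]]), 0)
})

test_that("all five centralities equal brute-force oracles on random graphs", {
  for (i in 1:12) {
    net <- rand_net(n = sample(4:10, 1), p = stats::runif(1, 0.2, 0.7),
                    seed = 400 + i)
    ob <- oracle_between_stress(net)
    expect_equal(unname(betweenness_centrality(net)$scores), ob$betweenness,
                 tolerance = 1e-10)
    expect_equal(unname(stress_centrality(net)$scores), ob$stress)
    expect_equal(unname(closeness_centrality(net)$scores), oracle_closeness(net),
                 tolerance = 1e-10)
    expect_equal(unname(mcc_centrality(net)$scores), oracle_mcc(net))
    A <- adj_bool(net)
    expect_equal(unname(degree_centrality(net)$scores), unname(rowSums(A)))
  }
})

test_that("centralities agree with igraph where igraph implements them", {
  skip_if_not_installed("igraph")
  for (i in 1:5) {
    net <- rand_net(n = 10, p = 0.4, seed = 90 + i)
    g <- igraph::graph_from_data_frame(net$edges[1:2], directed = FALSE,
                                       vertices = net$vertices)
    expect_equal(unname(betweenness_centrality(net)$scores),
                 unname(igraph::betweenness(g)), tolerance = 1e-10)
    expect_equal(unname(closeness_centrality(net)$scores),
                 unname(igraph::harmonic_centrality(g, normalized = FALSE)),
                 tolerance = 1e-10)
    expect_equal(unname(degree_centrality(net)$scores),
                 unname(igraph::degree(g)))
    # MCC recomputed from igraph's independent maximal-clique enumeration
    mcc_ig <- numeric(length(net$vertices))
    names(mcc_ig) <- net$vertices
    for (cl in igraph::max_cliques(g, min = 2)) {
      nms <- names(cl)
      mcc_ig[nms] <- mcc_ig[nms] + factorial(length(cl) - 1)
    }
    expect_equal(mcc_centrality(net)$scores, mcc_ig)
  }
})

test_that("rankings are deterministic with lexicographic tie-breaks", {
  net <- net_complete(5)             # all scores tie
  rk <- degree_centrality(net)
  expect_equal(rk$order, letters[1:5])
  expect_equal(top_k(rk, 3), c("a", "b", "c"))
  expect_equal(top_k(rk, 99), letters[1:5])
  expect_equal(top_k(c("z", "y", "x"), 2), c("z", "y"))
})

test_that("mcc guard trips on oversized networks unless forced", {
  net <- net_path3()
  expect_error(mcc_centrality(net, max_vertices = 2), "guard")
  expect_silent(mcc_centrality(net, max_vertices = 2, force = TRUE))
})

test_that("consensus_hubs implements the m-of-n rule on published rankings", {
  rk2 <- reference_rankings("module2")
  cons <- consensus_hubs(rk2, top_k = 20, min_methods = 3)
  hubs17 <- reference_hub_sets()$module2
  expect_setequal(cons$hubs, hubs17)
  expect_length(cons$hubs, 17)
  # the module-1 columns under the stated rule give 13 genes (incl. ACAN)
  rk1 <- reference_rankings("module1")
  cons1 <- consensus_hubs(rk1, top_k = 20, min_methods = 3)
  expect_length(cons1$hubs, 13)
  expect_true("ACAN" %in% cons1$hubs)
  expect_setequal(setdiff(cons1$hubs, "ACAN"), reference_hub_sets()$module1)
  # support bookkeeping invariants
  expect_true(all(cons$support[cons$hubs] >= 3))
  expect_true(all(cons$support <= length(rk2)))
  expect_true(all(cons$hubs %in% unlist(cons$per_method_top)))
})

test_that("consensus degenerate cases", {
  same <- list(m1 = letters[1:10], m2 = letters[1:10], m3 = letters[1:10])
  cons <- consensus_hubs(same, top_k = 4, min_methods = 3)
  expect_setequal(cons$hubs, letters[1:4])
  expect_error(consensus_hubs(same[1:2], top_k = 4, min_methods = 3),
               "min_methods")
})

test_that("complete graphs score all vertices equally under every method", {
  net <- net_complete(6)
  for (m in c("degree", "closeness", "betweenness", "stress", "mcc")) {
    sc <- centrality_rankings(net, m)[[1]]$scores
    expect_equal(length(unique(sc)), 1, info = m)
  }
})
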