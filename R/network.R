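# Interaction networks and hub-gene machinery: score-thresholded undirected
# graphs, the Dice neighbor-overlap score, five centralities (degree,
# harmonic closeness, Brandes betweenness, stress, maximal clique
# centrality), deterministic top-k ranking and the m-of-n consensus rule.
# Edge scores are used only for thresholding; all path computations are
# unweighted (the usual STRING/CytoHubba convention).

#' Build a score-thresholded interaction network
#'
#' Edges with score below `threshold` are dropped (comparison inclusive:
#' score >= threshold is kept). Self-loops are removed and duplicate
#' unordered pairs collapsed to their maximum score. Isolated vertices are
#' retained only if named in `vertices`.
#'
#' @param edges data frame with columns `from`, `to`, `score`
#'   (aliases `source`/`target`/`node1`/`node2` accepted).
#' @param threshold minimum retained score, default 0.40 (the "medium"
#'   STRING confidence cut; low/high/highest are 0.15/0.70/0.90).
#' @param vertices optional character vector of vertices to retain even if
#'   isolated after thresholding.
#' @return an `InteractionNetwork`: list with `vertices`, `edges`
#'   (data frame from/to/score with from < to), `threshold`.
#' @export
build_network <- function(edges, threshold = 0.40, vertices = NULL) {
  edges <- normalize_edge_frame(edges)
  if (any(edges$score < 0 | edges$score > 1, na.rm = TRUE))
    stop_parse("edge scores must lie in [0, 1]")
  if (anyNA(edges$score)) stop_parse("edge scores contain NA")
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stop_config("threshold must lie in [0, 1]")
  edges <- edges[edges$from != edges$to, , drop = FALSE]           # self-loops
  edges <- edges[edges$score >= threshold, , drop = FALSE]
  a <- pmin(edges$from, edges$to); b <- pmax(edges$from, edges$to)
  key <- paste(a, b, sep = "\r")
  o <- order(key, -edges$score, method = "radix")
  keep <- !duplicated(key[o])
  edges <- data.frame(from = a[o][keep], to = b[o][keep],
                      score = edges$score[o][keep], stringsAsFactors = FALSE)
  verts <- sort_c(c(edges$from, edges$to, vertices))
  structure(list(vertices = verts, edges = edges, threshold = threshold),
            class = "InteractionNetwork")
}

normalize_edge_frame <- function(edges) {
  nm <- names(edges)
  from <- nm[nm %in% c("from", "source", "node1")][1]
  to <- nm[nm %in% c("to", "target", "node2")][1]
  sc <- nm[nm %in% c("score", "weight", "combined_score")][1]
  if (is.na(from) || is.na(to))
    stop_parse("edge table needs from/to (or source/target) columns")
  out <- data.frame(from = as.character(edges[[from]]),
                    to = as.character(edges[[to]]),
                    stringsAsFactors = FALSE)
  out$score <- if (is.na(sc)) rep(1, nrow(out)) else as.numeric(edges[[sc]])
  out
}

#' Restrict a network to a vertex subset
#' @param net an `InteractionNetwork`.
#' @param genes vertices to keep (edges with both endpoints kept survive).
#' @return an `InteractionNetwork`.
#' @export
induce_subnetwork <- function(net, genes) {
  keep <- net$edges$from %in% genes & net$edges$to %in% genes
  structure(list(vertices = sort_c(intersect(net$vertices, genes)),
                 edges = net$edges[keep, , drop = FALSE],
                 threshold = net$threshold),
            class = "InteractionNetwork")
}

#' @export
print.InteractionNetwork <- function(x, ...) {
  cat(sprintf("InteractionNetwork: %d vertices, %d edges (score >= %g)\n",
              length(x$vertices), nrow(x$edges), x$threshold))
  invisible(x)
}

# Adjacency as a list of integer neighbor vectors over net$vertices.
adjacency_list <- function(net) {
  v <- net$vertices
  idx <- stats::setNames(seq_along(v), v)
  adj <- vector("list", length(v))
  for (i in seq_along(adj)) adj[[i]] <- integer(0)
  if (nrow(net$edges)) {
    fi <- idx[net$edges$from]; ti <- idx[net$edges$to]
    for (e in seq_along(fi)) {
      adj[[fi[e]]] <- c(adj[[fi[e]]], ti[e])
      adj[[ti[e]]] <- c(adj[[ti[e]]], fi[e])
    }
    adj <- lapply(adj, sort.int)
  }
  adj
}

#' Dice neighbor-overlap score between two vertices
#'
#' `D(u, v) = 2 |N_u ∩ N_v| / (|N_u| + |N_v|)` over open neighborhoods —
#' the neighbor-overlap distance used to relate interaction partners.
#' Symmetric, in \[0, 1\]; undefined (error) when both neighborhoods are
#' empty.
#'
#' @param net an `InteractionNetwork`.
#' @param u,v vertex names.
#' @return numeric score.
#' @export
neighbor_overlap_score <- function(net, u, v) {
  if (!(u %in% net$vertices) || !(v %in% net$vertices))
    stop_config("both vertices must be in the network")
  nb <- function(x) unique(c(net$edges$to[net$edges$from == x],
                             net$edges$from[net$edges$to == x]))
  nu <- nb(u); nv <- nb(v)
  if (length(nu) + length(nv) == 0L)
    stop_config(sprintf("neighbor overlap undefined: '%s' and '%s' are both isolated", u, v))
  2 * length(intersect(nu, nv)) / (length(nu) + length(nv))
}

new_ranking <- function(method, scores) {
  structure(list(method = method, scores = scores,
                 order = names(scores)[order_by_score(scores)]),
            class = "CentralityRanking")
}

#' @export
print.CentralityRanking <- function(x, ...) {
  cat(sprintf("CentralityRanking [%s] over %d vertices; top: %s\n",
              x$method, length(x$scores),
              paste(utils::head(x$order, 5), collapse = ", ")))
  invisible(x)
}

#' Degree centrality
#' @param net an `InteractionNetwork`.
#' @return a `CentralityRanking` (scores, deterministic order: score
#'   descending, ties lexicographic).
#' @export
degree_centrality <- function(net) {
  adj <- adjacency_list(net)
  new_ranking("degree", stats::setNames(lengths(adj), net$vertices))
}

# Single-source BFS returning distances, geodesic counts, visit order and
# predecessor lists (Brandes' data structures).
bfs_paths <- function(adj, s) {
  n <- length(adj)
  dist <- rep(-1L, n); sigma <- numeric(n); preds <- vector("list", n)
  dist[s] <- 0L; sigma[s] <- 1
  queue <- integer(n); qh <- 1L; qt <- 1L; queue[1] <- s
  order_out <- integer(n); no <- 0L
  while (qh <= qt) {
    v <- queue[qh]; qh <- qh + 1L
    no <- no + 1L; order_out[no] <- v
    for (w in adj[[v]]) {
      if (dist[w] < 0L) {
        dist[w] <- dist[v] + 1L
        qt <- qt + 1L; queue[qt] <- w
      }
      if (dist[w] == dist[v] + 1L) {
        sigma[w] <- sigma[w] + sigma[v]
        preds[[w]] <- c(preds[[w]], v)
      }
    }
  }
  list(dist = dist, sigma = sigma, order = order_out[seq_len(no)], preds = preds)
}

#' Closeness centrality (reciprocal-distance / harmonic form)
#'
#' `Clo(v) = sum_{w != v} 1 / d(v, w)`; unreachable vertices contribute 0,
#' so disconnected networks remain rankable (the classical `1 / sum d` form
#' degenerates there).
#'
#' @param net an `InteractionNetwork`.
#' @return a `CentralityRanking`.
#' @export
closeness_centrality <- function(net) {
  adj <- adjacency_list(net)
  n <- length(adj)
  sc <- numeric(n)
  for (s in seq_len(n)) {
    d <- bfs_paths(adj, s)$dist
    reach <- d > 0L
    sc[s] <- sum(1 / d[reach])
  }
  new_ranking("closeness", stats::setNames(sc, net$vertices))
}

# Brandes accumulation computing betweenness and stress together.
brandes_between_stress <- function(adj) {
  n <- length(adj)
  bet <- numeric(n); str <- numeric(n)
  for (s in seq_len(n)) {
    b <- bfs_paths(adj, s)
    delta_b <- numeric(n)  # pair-dependency (betweenness)
    delta_s <- numeric(n)  # geodesic counts through v from s (stress)
    for (i in rev(seq_along(b$order))) {
      w <- b$order[i]
      for (v in b$preds[[w]]) {
        frac <- b$sigma[v] / b$sigma[w]
        delta_b[v] <- delta_b[v] + frac * (1 + delta_b[w])
        delta_s[v] <- delta_s[v] + b$sigma[v] * (1 + delta_s[w] / b$sigma[w])
      }
      if (w != s) {
        bet[w] <- bet[w] + delta_b[w]
        str[w] <- str[w] + delta_s[w]
      }
    }
  }
  list(betweenness = bet / 2, stress = str / 2)  # unordered pairs
}

#' Betweenness centrality (unnormalized, unweighted, Brandes)
#' @param net an `InteractionNetwork`.
#' @return a `CentralityRanking`; scores count unordered source-target pairs.
#' @export
betweenness_centrality <- function(net) {
  res <- brandes_between_stress(adjacency_list(net))
  new_ranking("betweenness", stats::setNames(res$betweenness, net$vertices))
}

#' Stress centrality
#'
#' Number of shortest paths, over all unordered source-target pairs with
#' endpoints excluded, passing through each vertex.
#'
#' @param net an `InteractionNetwork`.
#' @return a `CentralityRanking`.
#' @export
stress_centrality <- function(net) {
  res <- brandes_between_stress(adjacency_list(net))
  new_ranking("stress", stats::setNames(res$stress, net$vertices))
}

# Bron-Kerbosch with pivoting; calls handler(clique) for each maximal clique
# (integer vertex indices, any size >= 1).
bron_kerbosch <- function(adj, handler) {
  n <- length(adj)
  recurse <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      handler(R)
      return(invisible(NULL))
    }
    pool <- c(P, X)
    # pivot: vertex maximizing |P ∩ N(u)|
    gains <- vapply(pool, function(u) sum(P %in% adj[[u]]), integer(1))
    u <- pool[which.max(gains)]
    for (v in setdiff(P, adj[[u]])) {
      recurse(c(R, v), intersect(P, adj[[v]]), intersect(X, adj[[v]]))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
    invisible(NULL)
  }
  recurse(integer(0), seq_len(n), integer(0))
}

#' Maximal clique centrality (MCC)
#'
#' `MCC(v) = sum over maximal cliques C containing v of (|C| - 1)!`, with
#' maximal cliques enumerated by Bron-Kerbosch with pivoting. Singleton
#' "cliques" are excluded, so isolated vertices score 0; for a vertex whose
#' neighbors are mutually non-adjacent the score reduces to its degree.
#' Exponential worst case: intended for desk-scale graphs, guarded at 5000
#' vertices.
#'
#' @param net an `InteractionNetwork`.
#' @param max_vertices guard on network size (default 5000).
#' @param force override the guard.
#' @return a `CentralityRanking`.
#' @export
mcc_centrality <- function(net, max_vertices = 5000L, force = FALSE) {
  n <- length(net$vertices)
  if (n > max_vertices && !force)
    stop_config(sprintf("mcc_centrality guard: %d vertices > %d (use force = TRUE)",
                        n, max_vertices))
  adj <- adjacency_list(net)
  env <- new.env()
  env$sc <- numeric(n)
  bron_kerbosch(adj, function(clq) {
    if (length(clq) >= 2L)
      env$sc[clq] <- env$sc[clq] + factorial(length(clq) - 1L)
  })
  new_ranking("mcc", stats::setNames(env$sc, net$vertices))
}

#' Compute a set of centrality rankings
#' @param net an `InteractionNetwork`.
#' @param methods subset of degree, closeness, betweenness, stress, mcc.
#' @return named list of `CentralityRanking` objects.
#' @export
centrality_rankings <- function(net, methods = c("mcc", "degree", "closeness",
                                                 "betweenness")) {
  fns <- list(degree = degree_centrality, closeness = closeness_centrality,
              betweenness = betweenness_centrality, stress = stress_centrality,
              mcc = mcc_centrality)
  bad <- setdiff(methods, names(fns))
  if (length(bad)) stop_config(sprintf("unknown centrality method '%s'", bad[1]))
  stats::setNames(lapply(methods, function(m) fns[[m]](net)), methods)
}

#' Top-k genes of a ranking
#' @param ranking a `CentralityRanking` or an already ordered character vector.
#' @param k list length (k >= |V| returns the full order).
#' @return character vector, first `k` of the deterministic order.
#' @export
top_k <- function(ranking, k) {
  ord <- if (inherits(ranking, "CentralityRanking")) ranking$order
         else as.character(ranking)
  utils::head(ord, k)
}

#' m-of-n consensus hub selection over centrality rankings
#'
#' Takes the top `top_k` genes of every ranking and selects as hubs the
#' genes present in at least `min_methods` of the per-method lists (the
#' "top 20 from every method, present in at least three methods" rule).
#'
#' @param rankings named list of `CentralityRanking` objects and/or ordered
#'   character vectors (e.g. transcribed published top-k columns).
#' @param top_k list length per method (default 20).
#' @param min_methods minimum supporting methods (default 3).
#' @return a `ConsensusHubSet`: list with `hubs` (sorted gene vector),
#'   `support` (named integer vector over all candidates), `per_method_top`,
#'   `top_k`, `min_methods`.
#' @export
consensus_hubs <- function(rankings, top_k = 20L, min_methods = 3L) {
  if (length(rankings) < min_methods)
    stop_config("min_methods exceeds the number of rankings supplied")
  tops <- lapply(rankings, function(r) {
    utils::head(if (inherits(r, "CentralityRanking")) r$order else as.character(r),
                top_k)
  })
  if (is.null(names(tops)) || any(!nzchar(names(tops))))
    names(tops) <- paste0("method", seq_along(tops))
  support_tab <- table(unlist(lapply(tops, unique), use.names = FALSE))
  support <- stats::setNames(as.integer(support_tab), names(support_tab))
  support <- support[order(names(support), method = "radix")]
  hubs <- sort_c(names(support)[support >= min_methods])
  structure(list(hubs = hubs, support = support, per_method_top = tops,
                 top_k = as.integer(top_k), min_methods = as.integer(min_methods)),
            class = "ConsensusHubSet")
}

#' @export
print.ConsensusHubSet <- function(x, ...) {
  cat(sprintf("ConsensusHubSet: %d hubs (top %d per method, >= %d of %d methods)\n",
              length(x$hubs), x$top_k, x$min_methods, length(x$per_method_top)))
  cat(" ", paste(x$hubs, collapse = ", "), "\n")
  invisible(x)
}
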