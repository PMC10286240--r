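# Independent brute-force oracles for the centrality and enrichment suites,
# plus small graph builders. These deliberately avoid the package's own
# algorithms: Floyd-Warshall distances, exhaustive geodesic enumeration and
# exhaustive subset checks for maximal cliques.

edge_df <- function(from, to, score = 1) {
  data.frame(from = from, to = to, score = score, stringsAsFactors = FALSE)
}

toy_net <- function(from, to) build_network(edge_df(from, to), threshold = 0)

# path a-b-c, star, triangle, complete graph
net_path3 <- function() toy_net(c("a", "b"), c("b", "c"))
net_complete <- function(n) {
  v <- letters[seq_len(n)]
  pr <- utils::combn(v, 2)
  toy_net(pr[1, ], pr[2, ])
}
net_star <- function(k) toy_net(rep("hub", k), sprintf("leaf%02d", seq_len(k)))

rand_net <- function(n, p, seed) {
  set.seed(seed)
  v <- sprintf("v%02d", seq_len(n))
  pr <- utils::combn(v, 2)
  keep <- stats::runif(ncol(pr)) < p
  build_network(edge_df(pr[1, keep], pr[2, keep]), threshold = 0, vertices = v)
}

adj_bool <- function(net) {
  v <- net$vertices
  A <- matrix(FALSE, length(v), length(v), dimnames = list(v, v))
  for (i in seq_len(nrow(net$edges))) {
    A[net$edges$from[i], net$edges$to[i]] <- TRUE
    A[net$edges$to[i], net$edges$from[i]] <- TRUE
  }
  A
}

fw_dist <- function(A) {
  n <- nrow(A)
  D <- ifelse(A, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_closeness <- function(net) {
  D <- fw_dist(adj_bool(net))
  sapply(seq_len(nrow(D)), function(i) {
    d <- D[i, -i]
    sum(1 / d[is.finite(d)])
  })
}

# every geodesic between s and t, by DFS descending the distance field
all_geodesics <- function(A, D, s, t) {
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible(NULL))
    }
    for (w in which(A[v, ])) {
      if (D[s, w] == D[s, v] + 1 && D[w, t] == D[v, t] - 1) walk(c(path, w))
    }
  }
  walk(s)
  paths
}

oracle_between_stress <- function(net) {
  A <- adj_bool(net)
  D <- fw_dist(A)
  n <- nrow(A)
  bet <- numeric(n); str <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t]) || D[s, t] < 2) next
    paths <- all_geodesics(A, D, s, t)
    for (p in paths) {
      interior <- p[-c(1, length(p))]
      str[interior] <- str[interior] + 1
      bet[interior] <- bet[interior] + 1 / length(paths)
    }
  }
  list(betweenness = bet, stress = str)
}

oracle_mcc <- function(net) {
  A <- adj_bool(net)
  n <- nrow(A)
  sc <- numeric(n)
  for (size in 2:max(2, n)) {
    if (size > n) break
    for (idx in utils::combn(n, size, simplify = FALSE)) {
      sub <- A[idx, idx, drop = FALSE]
      if (!all(sub[upper.tri(sub)])) next          # not a clique
      outside <- setdiff(seq_len(n), idx)
      if (any(vapply(outside, function(o) all(A[o, idx]), logical(1)))) next # not maximal
      sc[idx] <- sc[idx] + factorial(size - 1)
    }
  }
  sc
}

# PMF-summation oracle for the hypergeometric upper tail
oracle_hyper_tail <- function(N, M, n, k) {
  if (k <= 0) return(1)
  i <- k:min(M, n)
  sum(stats::dhyper(i, M, N - M, n))
}

jaccard <- function(a, b) {
  if (!length(a) && !length(b)) return(1)
  length(intersect(a, b)) / length(union(a, b))
}
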