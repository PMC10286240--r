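# DE statistics: BH adjustment, moderated t, NB Wald, duplicate collapse.

genesDE <- sprintf("G%06d", 1:400)

make_array_study <- function(de = character(0), effect = 2, sd = 0.1,
                             n = 10, seed = 1, ...) {
  d <- study_design(n_case = n, n_control = n, seed = seed)
  generate_expression_study(d, genesDE, de_genes = de, effect_log2fc = effect,
                            dispersion_or_sd = sd, ...)
}

test_that("bh_adjust matches hand-computed step-up examples", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("bh_adjust is permutation-equivariant and agrees with p.adjust", {
  set.seed(101)
  for (i in 1:20) {
    p <- stats::runif(sample(1:50, 1))^sample(1:3, 1)
    adj <- bh_adjust(p)
    expect_equal(adj, stats::p.adjust(p, "BH"))     # independent oracle
    perm <- sample(seq_along(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])
    expect_gte(min(adj), min(p))
    expect_true(all(adj <= 1))
  }
})

test_that("identical groups give zero logFC and no DEGs", {
  set.seed(8)
  half <- matrix(stats::rnorm(200, 7), nrow = 50)
  x <- cbind(half, half)                 # case block identical to control block
  dimnames(x) <- list(sprintf("g%02d", 1:50), sprintf("s%d", 1:8))
  st <- expression_study(x, rep(c("case", "control"), each = 4), "array")
  tab <- moderated_t_dge(st)
  expect_true(all(tab$log_fc == 0))
  expect_true(all(tab$direction == "not_significant"))
  expect_equal(unname(deg_summary(tab)), c(0, 0, 0))
})

test_that("a planted +2 gene is called up, consistent with the Welch oracle", {
  st <- make_array_study(de = "G000001", effect = 2, sd = 0.1, seed = 12)
  tab <- moderated_t_dge(st)
  rec <- tab[tab$gene == "G000001", ]
  expect_equal(rec$direction, "up")
  expect_lt(rec$p_value, 1e-3)
  welch <- stats::t.test(st$matrix["G000001", st$group == "case"],
                         st$matrix["G000001", st$group == "control"])
  expect_lt(welch$p.value, 1e-6)
})

test_that("direction thresholds follow the logFC/adj-p rule exactly", {
  expect_equal(classify_direction(0.9, 0.04), "not_significant")
  expect_equal(classify_direction(1.2, 0.04), "up")
  expect_equal(classify_direction(-1.2, 0.04), "down")
  expect_equal(classify_direction(1.0, 0.04), "up")      # logFC >= 1 inclusive
  expect_equal(classify_direction(2.5, 0.05), "not_significant")
})

test_that("moderated t reduces to the pooled t when the prior df is forced to 0", {
  st <- make_array_study(de = genesDE[1:5], seed = 3)
  tab <- moderated_t_dge(st, prior_df = 0)
  g <- "G000007"
  pooled <- stats::t.test(st$matrix[g, st$group == "case"],
                          st$matrix[g, st$group == "control"],
                          var.equal = TRUE)
  expect_equal(tab$p_value[tab$gene == g], pooled$p.value, tolerance = 1e-10)
  expect_equal(tab$log_fc[tab$gene == g],
               unname(diff(rev(pooled$estimate))), tolerance = 1e-10)
})

test_that("moderated t closely tracks the established empirical-Bayes oracle", {
  skip_if_not_installed("limma")
  set.seed(15)
  G <- 300
  sds <- exp(stats::rnorm(G, -0.5, 0.4))       # heteroskedastic -> finite d0
  x <- matrix(stats::rnorm(G * 12, 0, rep(sds, 12)), G) + 8
  x[1:10, 1:6] <- x[1:10, 1:6] + 1.5
  dimnames(x) <- list(sprintf("g%03d", 1:G), sprintf("s%02d", 1:12))
  st <- expression_study(x, rep(c("case", "control"), each = 6), "array")
  tab <- moderated_t_dge(st, collapse = FALSE)
  fit <- limma::eBayes(limma::lmFit(x, cbind(1, rep(c(1, 0), each = 6))))
  p_ref <- fit$p.value[tab$gene, 2]
  expect_gt(stats::cor(log(tab$p_value), log(p_ref)), 0.999)
  expect_lt(max(abs(tab$p_value - p_ref) / pmax(p_ref, 1e-12)), 0.05)
  expect_equal(tab$log_fc, unname(fit$coefficients[tab$gene, 2]),
               tolerance = 1e-10)
})

test_that("raw p-values are approximately uniform under the global null", {
  d <- study_design(n_case = 10, n_control = 10, seed = 77)
  genes2k <- sprintf("G%06d", 1:2000)
  st <- generate_expression_study(d, genes2k, dispersion_or_sd = 0.3)
  tab <- moderated_t_dge(st)
  ks <- suppressWarnings(stats::ks.test(tab$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("moderated t rejects degenerate inputs", {
  x <- matrix(1, 10, 8, dimnames = list(paste0("g", 1:10), paste0("s", 1:8)))
  st <- expression_study(x, rep(c("case", "control"), each = 4), "array")
  expect_error(moderated_t_dge(st), "degenerate")
  x2 <- matrix(stats::rnorm(30), 10, 3,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:3)))
  st2 <- expression_study(x2, c("case", "control", "control"), "array")
  expect_error(moderated_t_dge(st2), "2 samples per group")
})

test_that("median-of-ratios size factors recover an exact scaling", {
  y <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  sf <- crosshub:::estimate_size_factors(y)
  expect_equal(unname(sf[2] / sf[1]), 2)     # proportional to (1, 2)
  bad <- matrix(c(0, 5, 3, 0), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(crosshub:::estimate_size_factors(bad), "zero")
})

test_that("NB Wald recovers a planted 4-fold change on average over 10 seeds", {
  est <- vapply(1:10, function(s) {
    d <- study_design(platform_kind = "counts", n_case = 10, n_control = 10,
                      seed = 1000 + s)
    st <- generate_expression_study(d, genesDE[1:100], de_genes = "G000001",
                                    effect_log2fc = 2, dispersion_or_sd = 0.05)
    tab <- negbin_wald_dge(st)
    tab$log_fc[tab$gene == "G000001"]
  }, numeric(1))
  expect_lt(abs(mean(est) - 2), 0.3)
})

test_that("NB Wald controls false positives under the global null", {
  frac <- vapply(1:10, function(s) {
    d <- study_design(platform_kind = "counts", n_case = 5, n_control = 5,
                      seed = 2000 + s)
    st <- generate_expression_study(d, genesDE[1:200], dispersion_or_sd = 0.1)
    tab <- negbin_wald_dge(st)
    mean(tab$adj_p < 0.05)
  }, numeric(1))
  expect_lte(mean(frac), 0.005)
})

test_that("all-zero genes are reported with p = 1, not dropped", {
  y <- matrix(stats::rnbinom(80, mu = 50, size = 10), 10, 8,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:8)))
  y[3, ] <- 0
  st <- expression_study(y, rep(c("case", "control"), each = 4), "counts")
  tab <- negbin_wald_dge(st)
  expect_equal(nrow(tab), 10)
  expect_equal(tab$p_value[tab$gene == "g3"], 1)
  expect_equal(tab$log_fc[tab$gene == "g3"], 0)
})

test_that("collapse_duplicates keeps max |logFC| with documented tie-breaks", {
  rec <- data.frame(
    gene = c("A", "A", "B", "C", "C", "C"),
    probe = c("p1", "p2", "p3", "p4", "p5", "p6"),
    log_fc = c(1.5, -0.2, 0.4, 1.0, -1.0, 1.0),
    p_value = c(0.1, 0.2, 0.5, 0.03, 0.01, 0.03),
    adj_p = c(0.1, 0.2, 0.5, 0.03, 0.01, 0.03),
    direction = "not_significant", stringsAsFactors = FALSE)
  out <- collapse_duplicates(rec)
  expect_equal(nrow(out), 3)
  expect_equal(out$log_fc[out$gene == "A"], 1.5)
  # C: all |logFC| tie at 1; p5 wins on smaller adj_p
  expect_equal(out$probe[out$gene == "C"], "p5")
  # no duplicates -> identity (up to ordering)
  single <- rec[c(1, 3), ]
  out2 <- collapse_duplicates(single)
  expect_equal(sort(out2$probe), sort(single$probe))
})

test_that("a duplicate-probe study collapses to one row per gene", {
  st <- make_array_study(de = genesDE[1:10], seed = 5, duplicate_probes = TRUE)
  tab <- moderated_t_dge(st)
  expect_equal(nrow(tab), length(genesDE))
  expect_false(anyDuplicated(tab$gene) > 0)
})

test_that("deg_summary counts planted directions correctly", {
  de <- genesDE[1:15]
  st <- make_array_study(de = de, effect = c(rep(2, 10), rep(-2, 5)),
                         sd = 0.1, seed = 21)
  s <- deg_summary(moderated_t_dge(st))
  expect_equal(unname(s["n_up"]), 10)
  expect_equal(unname(s["n_down"]), 5)
  expect_equal(unname(s["n_total"]), unname(s["n_up"] + s["n_down"]))
})
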