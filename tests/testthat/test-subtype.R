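make_subtype_fixture <- function(probe_means, clusters = NULL) {
  # probe_means: named list probe -> (gene, mean)
  samples <- paste0("s", 1:8)
  if (is.null(clusters)) {
    clusters <- setNames(rep(c("c1", "c2", "c4", "c5"), each = 2), samples)
  }
  expr <- do.call(rbind, lapply(probe_means, function(pm) {
    rep(pm$mean, length(samples))
  }))
  rownames(expr) <- names(probe_means)
  colnames(expr) <- samples
  probe_map <- vapply(probe_means, `[[`, character(1), "gene")
  subtype_dataset(expr, clusters, probe_map)
}

test_that("probe-set selection picks the highest-mean probe", {
  ds <- make_subtype_fixture(list(
    "218755_at" = list(gene = "KIF20A", mean = 9.1),
    "223688_s_at" = list(gene = "LY6K", mean = 7.0),
    "214240_at" = list(gene = "LY6K", mean = 3.2),
    "235700_at" = list(gene = "CT45", mean = 5.5)))
  expect_equal(select_probe_set("KIF20A", ds), "218755_at")   # single probe
  expect_equal(select_probe_set("LY6K", ds), "223688_s_at")   # max rule
  expect_equal(select_probe_set("CT45", ds), "235700_at")
  expect_error(select_probe_set("ABSENT", ds), "no mapped probe")
})

test_that("probe-selection ties break to the smallest probe id", {
  ds <- make_subtype_fixture(list(
    "B_at" = list(gene = "G", mean = 5),
    "A_at" = list(gene = "G", mean = 5)))
  expect_equal(select_probe_set("G", ds), "A_at")
})

test_that("dataset constructor rejects non-malignant cluster labels", {
  expr <- matrix(1, 1, 4, dimnames = list("p1", paste0("s", 1:4)))
  cl <- setNames(c("c1", "c2", "c3", "c5"), paste0("s", 1:4))
  expect_error(subtype_dataset(expr, cl, c(p1 = "G")), "c3")
  cl_ok <- setNames(c("c1", "c1", "c1", "c1"), paste0("s", 1:4))
  expect_error(subtype_dataset(expr, cl_ok, c(p1 = "G")), "two clusters")
})

test_that("Kruskal-Wallis handles degenerate and identical groups", {
  res <- kruskal_wallis(list(c(2, 2, 2), c(2, 2), c(2, 2, 2)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
})

test_that("Kruskal-Wallis H agrees with kruskal.test and the rank oracle", {
  set.seed(61)
  for (i in 1:10) {
    groups <- lapply(sample(3:6, 3, replace = TRUE), function(n) {
      round(rnorm(n, sd = 2), 1)  # rounding induces occasional ties
    })
    res <- kruskal_wallis(groups, exact = FALSE)
    ref <- kruskal.test(unlist(groups),
                        rep(seq_along(groups), lengths(groups)))
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p.value, ref$p.value, tolerance = 1e-12)
    expect_equal(res$statistic, kw_h_oracle(groups), tolerance = 1e-12)
  }
})

test_that("exact Kruskal-Wallis p matches full enumeration for small n", {
  groups <- list(c(1.2, 3.4, 2.2), c(5.6, 4.1, 7.7), c(0.3, 6.6, 2.9))
  res <- kruskal_wallis(groups)   # total n = 9 -> exact by default
  expect_match(res$method, "exact")
  expect_equal(res$p.value, kw_exact_oracle(groups), tolerance = 1e-12)

  set.seed(62)
  for (i in 1:3) {
    groups <- list(rnorm(3), rnorm(4), rnorm(3))
    expect_equal(kruskal_wallis(groups)$p.value, kw_exact_oracle(groups),
                 tolerance = 1e-12)
  }
})

test_that("H is invariant under monotone transformation of the data", {
  set.seed(63)
  groups <- list(rexp(8), rexp(8) + 0.5, rexp(8))
  h1 <- kruskal_wallis(groups, exact = FALSE)$statistic
  h2 <- kruskal_wallis(lapply(groups, log), exact = FALSE)$statistic
  h3 <- kruskal_wallis(lapply(groups, function(x) x^3),
                       exact = FALSE)$statistic
  expect_equal(h1, h2, tolerance = 1e-12)
  expect_equal(h1, h3, tolerance = 1e-12)
})

test_that("a strongly shifted cluster is detected at n = 20 per group", {
  set.seed(64)
  groups <- c(lapply(1:3, function(i) rnorm(20)), list(rnorm(20) + 3))
  expect_lt(kruskal_wallis(groups, exact = FALSE)$p.value, 0.01)
})

test_that("Dunn-Bonferroni structure: pair count, adjustment, null case", {
  groups <- list(a = c(1, 4, 2), b = c(3, 6, 5), c = c(8, 7, 9),
                 d = c(10, 12, 11))
  dn <- dunn_bonferroni(groups)
  expect_equal(nrow(dn), 6)   # choose(4, 2)
  expect_true(all(dn$p.adjusted >= dn$p.value - 1e-15))
  expect_true(all(dn$p.adjusted <= 1))

  same <- dunn_bonferroni(list(a = c(1, 2, 3), b = c(1, 2, 3),
                               c = c(1, 2, 3)))
  expect_true(all(same$p.adjusted == 1))
})

test_that("a planted c5 shift gives that cluster the smallest Dunn p-values", {
  sim <- simulate_subtype_dataset(
    n_per_cluster = 20, n_genes = 5,
    planted = data.frame(gene = "GENE002", cluster = "c5", shift = 2.5),
    seed = 65)
  probe <- select_probe_set("GENE002", sim$dataset)
  groups <- split(sim$dataset$expr[probe, ], sim$dataset$clusters)
  dn <- dunn_bonferroni(groups)
  with_c5 <- dn$group1 == "c5" | dn$group2 == "c5"
  expect_lt(max(dn$p.adjusted[with_c5]), min(dn$p.adjusted[!with_c5]))
})

test_that("the DE scan ranks a planted gene first among nulls", {
  sim <- simulate_subtype_dataset(
    n_per_cluster = 20, n_genes = 50,
    planted = data.frame(gene = "GENE007", cluster = "c5", shift = 2),
    seed = 66)
  scan <- subtype_de_scan(sim$dataset)
  expect_equal(scan$table$gene[1], "GENE007")
  expect_true("GENE007" %in% names(scan$posthoc))
})
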