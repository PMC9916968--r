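test_that("Fisher exact p matches enumeration on worked tables", {
  # perfectly discordant 5/5 table: 6 admissible tables under the margins
  tab <- matrix(c(0, 5, 5, 0), 2)
  expect_equal(fisher_exact_2x2(tab)$p.value, fisher_oracle(tab),
               tolerance = 1e-12)
  # identical rows carry no association
  expect_equal(fisher_exact_2x2(matrix(c(3, 3, 7, 7), 2))$p.value, 1)
  tab2 <- matrix(c(1, 11, 9, 3), 2)
  expect_equal(fisher_exact_2x2(tab2)$p.value, fisher_oracle(tab2),
               tolerance = 1e-12)
})

test_that("Fisher exact agrees with stats::fisher.test on random tables", {
  set.seed(41)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab)$p.value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-12)
  }
})

test_that("zero margins and invalid counts are handled", {
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 5), 2))$p.value, 1)
  expect_error(fisher_exact_2x2(matrix(c(1.5, 2, 3, 4), 2)), "integer")
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)), "integer|negative")
  expect_error(fisher_exact_2x2(matrix(1:6, 2)), "2x2")
})

test_that("chi-squared statistic equals the hand O-E arithmetic", {
  tab <- matrix(c(10, 20, 30, 40), 2)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  res <- chi_squared_test(tab)
  expect_equal(res$statistic, sum((tab - E)^2 / E))
  expect_equal(res$df, 1)
  expect_equal(res$p.value, pchisq(res$statistic, 1, lower.tail = FALSE))

  # independence: O = E exactly
  ind <- matrix(c(10, 20, 20, 40), 2)
  res0 <- chi_squared_test(ind)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p.value, 1)

  expect_equal(chi_squared_test(matrix(1:6, 3))$df, 2)
  expect_error(chi_squared_test(matrix(c(0, 0, 3, 5), 2)), "exact")
})

test_that("Spearman rho handles perfect and reversed orderings", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_rho(x, x)$rho, 1)
  expect_equal(spearman_rho(x, -x)$rho, -1)
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearman_rho(1:3, 1:4), "equal length")
})

test_that("Spearman matches the exhaustive permutation oracle with ties", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 4, 4, 6, 5)   # one tie
  res <- spearman_rho(x, y)
  expect_equal(res$rho, spearman_oracle_rho(x, y), tolerance = 1e-12)
  expect_equal(res$p.value, spearman_exact_oracle(x, y), tolerance = 1e-12)

  set.seed(42)
  for (i in 1:5) {
    n <- sample(4:7, 1)
    x <- rnorm(n)
    y <- sample(c(rnorm(n - 1), x[1]))  # occasional tie
    res <- spearman_rho(x, y)
    expect_equal(res$rho, spearman_oracle_rho(x, y), tolerance = 1e-12)
    expect_equal(res$p.value, spearman_exact_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("Kaplan-Meier matches hand product-limit computations", {
  # 10 events, no censoring: steps of 1/10, median at t = 5
  k <- km_curve(1:10, rep(TRUE, 10))
  expect_equal(k$surv, seq(0.9, 0, by = -0.1))
  expect_equal(k$median, 5)
  expect_equal(k$surv[1], 1 - 1 / 10)

  # all censored: flat at 1, median undefined
  k2 <- km_curve(c(2, 4, 6), rep(FALSE, 3))
  expect_true(all(k2$surv == 1))
  expect_true(is.na(k2$median))

  # one event at t=3 among 3 subjects, others censored later: S(3) = 2/3
  k3 <- km_curve(c(3, 5, 7), c(TRUE, FALSE, FALSE))
  expect_equal(k3$surv[k3$time == 3], 2 / 3)

  # censoring reduces the risk set without a step
  k4 <- km_curve(c(1, 2, 3, 4), c(TRUE, FALSE, TRUE, TRUE))
  o <- km_oracle(c(1, 2, 3, 4), c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(k4$surv[match(o$time, k4$time)], o$surv)
})

test_that("KM with zero censoring equals the empirical survival function", {
  set.seed(44)
  t <- round(rexp(30, 0.1), 2)
  k <- km_curve(t, rep(TRUE, 30))
  for (i in seq_along(k$time)) {
    expect_equal(k$surv[i], mean(t > k$time[i]))
  }
  expect_equal(k$median, min(k$time[k$surv <= 0.5]))
})

test_that("log-rank statistic matches the hand O-E table", {
  tA <- c(1, 2); tB <- c(3, 4)
  res <- logrank_test(c(tA, tB), rep(TRUE, 4), rep(c("A", "B"), each = 2))
  expect_equal(res$statistic, logrank_oracle(tA, c(1, 1), tB, c(1, 1)))

  set.seed(45)
  t1 <- rexp(20); e1 <- runif(20) < 0.8
  t2 <- rexp(20, 2); e2 <- runif(20) < 0.8
  res2 <- logrank_test(c(t1, t2), c(e1, e2), rep(1:2, each = 20))
  expect_equal(res2$statistic, logrank_oracle(t1, e1, t2, e2),
               tolerance = 1e-9)
})

test_that("log-rank is symmetric and degenerates sensibly", {
  t <- c(1, 3, 5, 7); e <- c(TRUE, TRUE, FALSE, TRUE)
  g <- c("a", "b", "a", "b")
  res1 <- logrank_test(t, e, g)
  res2 <- logrank_test(t, e, ifelse(g == "a", "b", "a"))
  expect_equal(res1$statistic, res2$statistic)

  # identical groups: statistic 0
  res3 <- logrank_test(c(1, 2, 1, 2), c(TRUE, TRUE, TRUE, TRUE),
                       rep(1:2, each = 2))
  expect_lt(res3$statistic, 1e-20)
  expect_equal(res3$p.value, 1)

  expect_warning(res4 <- logrank_test(c(1, 2), c(FALSE, FALSE), c("a", "b")),
                 "no events")
  expect_equal(res4$p.value, 1)
  expect_error(logrank_test(1:3, rep(TRUE, 3), c("a", "b", "c")), "two groups")
})

test_that("all battery p-values lie in (0, 1]", {
  tm <- simulate_tma_cohort(n_samples = 58, hazard_ratio_high_vs_low = 0.4,
                            platinum_or = 4, seed = 51)
  bat <- tma_association_battery(tm$tma)
  expect_true(all(bat$p > 0 & bat$p <= 1))
  expect_true(all(c("grouping", "covariate", "test", "p") %in% names(bat)))
  expect_setequal(unique(bat$grouping), c("intensity_dichotomy", "q_ge_150"))
  expect_true("logrank" %in% bat$test)
  # Bonferroni option: adjusted >= raw, capped at 1
  bat2 <- tma_association_battery(tm$tma, bonferroni = TRUE)
  expect_true(all(bat2$p_adjusted >= bat2$p))
  expect_true(all(bat2$p_adjusted <= 1))
})
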