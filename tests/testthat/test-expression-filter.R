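test_that("neoantigen exclusion retains self-antigens in order", {
  cands <- antigen_candidates(c("A", "B", "C", "N1", "N2"),
                              c("self", "self", "self",
                                "neoantigen", "neoantigen"))
  res <- exclude_neoantigens(cands)
  expect_equal(res$retained$id, c("A", "B", "C"))
  expect_equal(res$n_excluded, 2)

  empty <- exclude_neoantigens(antigen_candidates(character()))
  expect_equal(nrow(empty$retained), 0)
  expect_equal(empty$n_excluded, 0)

  # viral antigens are dropped too
  res2 <- exclude_neoantigens(antigen_candidates(c("A", "V"),
                                                 c("self", "viral")))
  expect_equal(res2$retained$id, "A")
})

test_that("duplicate candidate ids are rejected by name", {
  expect_error(antigen_candidates(c("A", "A", "B"), "self"), "A")
})

test_that("a roster with 70 neoantigens among 237 leaves 167", {
  cands <- antigen_candidates(
    sprintf("G%03d", 1:237),
    c(rep("self", 167), rep("neoantigen", 70)))
  res <- exclude_neoantigens(cands)
  expect_equal(nrow(res$retained), 167)
  expect_equal(res$n_excluded, 70)
})

test_that("tier assignment follows the strict max-based rule", {
  expect_equal(assign_tier(c(a = 0, b = 0)), "low")
  expect_equal(assign_tier(c(liver = 5, testis = 390)), "medium")
  # boundary values land in the next (more expressed) tier
  expect_equal(assign_tier(c(a = 40)), "medium")
  expect_equal(assign_tier(c(a = 39.999)), "low")
  expect_equal(assign_tier(c(a = 400)), "excluded")
  expect_equal(assign_tier(c(a = 399.999)), "medium")
  expect_error(assign_tier(numeric()), "empty")
  expect_error(assign_tier(c(a = -1)), "negative")
})

test_that("tier assignment matches a one-line oracle on random profiles", {
  set.seed(11)
  for (i in 1:100) {
    tpm <- exp(runif(sample(1:6, 1), log(0.1), log(2000)))
    names(tpm) <- paste0("t", seq_along(tpm))
    m <- max(tpm)
    oracle <- if (m < 40) "low" else if (m < 400) "medium" else "excluded"
    expect_identical(assign_tier(tpm), oracle)
  }
})

test_that("tier is monotone in any tissue's TPM", {
  set.seed(12)
  order_of <- c(low = 1, medium = 2, excluded = 3)
  for (i in 1:50) {
    tpm <- setNames(exp(runif(4, log(1), log(1000))), paste0("t", 1:4))
    bumped <- tpm
    j <- sample(4, 1)
    bumped[j] <- bumped[j] * runif(1, 1, 10)
    expect_gte(order_of[[assign_tier(bumped)]], order_of[[assign_tier(tpm)]])
  }
})

test_that("tumor gate applies tier-specific OR-of-strict cutoffs", {
  expect_equal(tumor_gate(0.6, 0.9, "low"), "retained")     # median clause
  expect_equal(tumor_gate(0.4, 1.2, "low"), "retained")     # mean clause
  expect_equal(tumor_gate(0.5, 1.0, "low"), "omitted")      # strict >
  expect_equal(tumor_gate(4, 9, "medium"), "omitted")
  expect_equal(tumor_gate(6, 2, "medium"), "retained")
  expect_equal(tumor_gate(5, 10, "medium"), "omitted")      # boundary
  expect_equal(tumor_gate(NA, NA, "low"), "no_data")
  expect_error(tumor_gate(1, 1, "excluded"), "low- or medium")
})

test_that("tumor gate is monotone in median and mean FPKM", {
  set.seed(13)
  lvl <- c(omitted = 0, no_data = 0, retained = 1)
  for (i in 1:50) {
    med <- runif(1, 0, 8); mn <- runif(1, 0, 15)
    tier <- sample(c("low", "medium"), 1)
    a <- tumor_gate(med, mn, tier)
    b <- tumor_gate(med * 1.5, mn, tier)
    cc <- tumor_gate(med, mn * 1.5, tier)
    expect_gte(lvl[[b]], lvl[[a]])
    expect_gte(lvl[[cc]], lvl[[a]])
  }
})

make_cascade_fixture <- function(seed = 5) {
  healthy <- simulate_healthy_expression(
    n_genes_per_tier = c(low = 12, medium = 10, high = 8), seed = seed)
  tumor <- simulate_tumor_cohort(
    healthy$truth$tiers, n_samples = 30,
    n_expressed_by_tier = c(low = 5, medium = 4),
    n_missing_by_tier = c(low = 1, medium = 1), seed = seed + 1)
  roster <- antigen_candidates(
    c(names(healthy$truth$tiers), "NEO1", "NEO2"),
    c(rep("self", length(healthy$truth$tiers)), "neoantigen", "neoantigen"))
  list(healthy = healthy, tumor = tumor, roster = roster)
}

test_that("cascade recovers planted truth and conserves counts", {
  fx <- make_cascade_fixture()
  rep <- run_cascade(fx$roster, fx$healthy$profile, fx$tumor$fpkm)

  st <- rep$stages
  expect_equal(st$n_in, st$n_excluded + st$n_out)
  expect_equal(st$n_in[-1], st$n_out[-nrow(st)])

  # zero-noise recovery of planted tiers and gate statuses
  truth_tiers <- fx$healthy$truth$tiers
  expected <- ifelse(truth_tiers == "high", "excluded", truth_tiers)
  expect_identical(rep$tiers[names(truth_tiers)], expected)
  status <- fx$tumor$truth$gate_status
  expect_setequal(rep$retained$id, names(status)[status == "retained"])
  nd <- rep$exclusions$id[rep$exclusions$reason == "no_tumor_data"]
  expect_setequal(nd, names(status)[status == "no_data"])
  bc <- rep$exclusions$id[rep$exclusions$reason == "below_tumor_cutoff"]
  expect_setequal(bc, names(status)[status == "omitted"])
})

test_that("cascade output matches brute-force per-gene re-evaluation", {
  fx <- make_cascade_fixture(seed = 21)
  rep <- run_cascade(fx$roster, fx$healthy$profile, fx$tumor$fpkm)
  summ <- summarize_tumor_matrix(fx$tumor$fpkm)
  for (g in names(fx$healthy$truth$tiers)) {
    m <- max(fx$healthy$profile[g, ])
    tier <- if (m < 40) "low" else if (m < 400) "medium" else "excluded"
    if (tier == "excluded") {
      expect_true(g %in% rep$exclusions$id[rep$exclusions$reason ==
                                             "high_healthy_expression"])
      next
    }
    row <- summ[summ$gene == g, ]
    cut <- if (tier == "low") c(0.5, 1) else c(5, 10)
    if (nrow(row) == 0) {
      expect_true(g %in% rep$exclusions$id[rep$exclusions$reason ==
                                             "no_tumor_data"])
    } else if (row$median_fpkm > cut[1] || row$mean_fpkm > cut[2]) {
      expect_true(g %in% rep$retained$id)
    } else {
      expect_true(g %in% rep$exclusions$id[rep$exclusions$reason ==
                                             "below_tumor_cutoff"])
    }
  }
})

test_that("candidates missing from the healthy profile are a hard error", {
  fx <- make_cascade_fixture()
  roster <- antigen_candidates(c(fx$roster$id[fx$roster$antigen_class == "self"],
                                 "GHOST"), "self")
  expect_error(run_cascade(roster, fx$healthy$profile, fx$tumor$fpkm),
               "GHOST")
})

test_that("a roster planted all-high yields zero survivors", {
  healthy <- simulate_healthy_expression(
    n_genes_per_tier = c(low = 0, medium = 0, high = 6), seed = 2)
  tumor <- simulate_tumor_cohort(healthy$truth$tiers, n_samples = 10,
                                 n_expressed_by_tier = c(low = 0, medium = 0),
                                 n_missing_by_tier = c(low = 0, medium = 0),
                                 seed = 3)
  rep <- run_cascade(names(healthy$truth$tiers), healthy$profile, tumor$fpkm)
  expect_equal(nrow(rep$retained), 0)
  expect_true(all(rep$exclusions$reason == "high_healthy_expression"))
})
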