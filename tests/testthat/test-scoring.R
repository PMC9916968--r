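test_that("default rubric carries the canonical structure", {
  r <- default_rubric()
  maxima <- criterion_maxima(r)
  expect_equal(unname(maxima),
               c(2.5, 2.25, 2.25, 1, 0.8, 0.6, 0.6))
  expect_equal(round(sum(maxima), 2), 10.00)
  # every criterion offers a zero-point "not applicable" selection
  for (cr in unique(r$criterion)) {
    block <- r[r$criterion == cr, ]
    expect_true("not applicable" %in% block$label)
    expect_equal(block$points[block$label == "not applicable"], 0)
    expect_equal(block$points[1], max(block$points))
  }
})

test_that("rubric constructor enforces its invariants", {
  expect_error(rubric(data.frame(criterion = "A", label = "x", points = -1)),
               "non-negative")
  expect_error(
    rubric(data.frame(criterion = c("A", "A"), label = c("lo", "hi"),
                      points = c(1, 2))),
    "maximum")
  expect_error(
    rubric(data.frame(criterion = c("A", "A"), label = c("x", "x"),
                      points = c(2, 1))),
    "duplicate")
})

test_that("normalization scales proportionally and is idempotent", {
  r <- rubric(data.frame(criterion = c("A", "A", "B"),
                         label = c("top", "mid", "top"),
                         points = c(4, 2, 1)))
  n <- normalize_rubric(r, 10)
  expect_equal(unname(criterion_maxima(n)), c(8, 2))
  expect_equal(n$points[n$label == "mid" & n$criterion == "A"], 4)

  # rubric with maxima summing to 12.5 scaled by 0.8
  r2 <- rubric(data.frame(criterion = c("A", "B"), label = c("t", "t"),
                          points = c(10, 2.5)))
  n2 <- normalize_rubric(r2, 10)
  expect_equal(sum(criterion_maxima(n2)), 10.00)
  expect_equal(n2$points[n2$criterion == "A" & n2$label == "t"], 10 * 0.8)

  # idempotence up to rounding
  once <- normalize_rubric(default_rubric(), 10)
  twice <- normalize_rubric(once, 10)
  expect_equal(twice$points, once$points)

  expect_error(normalize_rubric(
    rubric(data.frame(criterion = "A", label = "t", points = 0))),
    "zero")
})

test_that("worked annotation fixtures score 8.34, 8.07 and 7.70", {
  scores <- vapply(worked_example_annotations(),
                   function(a) score_candidate(a)$total, numeric(1))
  expect_identical(unname(scores), c(8.34, 8.07, 7.70))
})

test_that("unknown and not-applicable selections score zero", {
  r <- default_rubric()
  all_unknown <- candidate_annotation(
    "X", setNames(rep("unknown", 7), unique(r$criterion)))
  expect_equal(score_candidate(all_unknown, r)$total, 0)
  all_na <- candidate_annotation(
    "Y", setNames(rep("not applicable", 7), unique(r$criterion)))
  expect_equal(score_candidate(all_na, r)$total, 0)
  # criteria absent from the selection default to unknown
  partial <- candidate_annotation("Z", c(Immunogenicity =
    "HLA-restricted T cell-immunity verifiable"))
  expect_equal(score_candidate(partial, r)$total, 2.5)
})

test_that("insufficient-data candidates are unscored", {
  s <- score_candidate(candidate_annotation("X", insufficient_data = TRUE))
  expect_false(s$scored)
  expect_true(is.na(s$total))
})

test_that("invalid selections name the criterion and label", {
  ann <- candidate_annotation("X", c(Immunogenicity = "made-up tier"))
  expect_error(score_candidate(ann), "Immunogenicity.*made-up tier")
  bad <- candidate_annotation("X", c(NotACriterion = "whatever"))
  expect_error(score_candidate(bad), "NotACriterion")
})

test_that("totals are bounded and monotone in subcriterion upgrades", {
  set.seed(31)
  r <- default_rubric()
  crs <- unique(r$criterion)
  rubric_max <- sum(criterion_maxima(r))
  for (i in 1:25) {
    sel <- vapply(crs, function(cr) {
      block <- r[r$criterion == cr, ]
      sample(c(block$label, "unknown"), 1)
    }, character(1))
    s <- score_candidate(candidate_annotation("X", sel), r)
    expect_gte(s$total, 0)
    expect_lte(s$total, rubric_max)
    # upgrade one criterion to its top tier: total never decreases
    cr <- sample(crs, 1)
    up <- sel
    up[[cr]] <- r$label[r$criterion == cr][1]
    s2 <- score_candidate(candidate_annotation("X", up), r)
    expect_gte(s2$total, s$total)
  }
})

test_that("ranking uses shared competition ranks and appends unscored", {
  scored <- data.frame(id = c("A", "B", "C"), total = c(8.34, 8.34, 8.07))
  rk <- rank_candidates(scored)
  expect_equal(rk$rank, c(1, 1, 3))

  one <- rank_candidates(data.frame(id = "A", total = 5))
  expect_equal(one$rank, 1)

  mixed <- rank_candidates(data.frame(id = c("B", "A", "U"),
                                      total = c(3, 5, NA)))
  expect_equal(mixed$id, c("A", "B", "U"))
  expect_equal(mixed$rank, c(1, 2, NA))
})

test_that("ranking is a permutation with non-decreasing ranks", {
  gen <- simulate_annotations(20, n_insufficient = 3, seed = 8)
  rk <- rank_candidates(score_candidates(gen$annotations))
  expect_setequal(rk$id, gen$truth$expected$id)
  expect_equal(anyDuplicated(rk$id), 0)
  scored_ranks <- rk$rank[!is.na(rk$rank)]
  expect_true(all(diff(scored_ranks) >= 0))
  expect_equal(sum(is.na(rk$rank)), 3)
})
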