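test_that("node impurity follows the quadratic index", {
  expect_equal(node_gini(c(0, 10)), 0)
  expect_equal(node_gini(c(5, 5)), 0.5)
  expect_equal(node_gini(c(1, 3)), 0.375)
  expect_equal(node_gini(c(2, 3, 5)), 1 - (0.2^2 + 0.3^2 + 0.5^2))
  expect_error(node_gini(c(0, 0)), class = "besplit_validation_error")
  expect_error(node_gini(c(-1, 2)), class = "besplit_validation_error")
})

test_that("candidates are midpoints between adjacent distinct values", {
  expect_equal(candidate_splits(c(1, 2, 3)), c(1.5, 2.5))
  expect_equal(candidate_splits(c(2, 2, 4)), 3)
  expect_equal(candidate_splits(7), numeric(0))
  expect_equal(candidate_splits(c(5, 5, 5)), numeric(0))
  expect_equal(candidate_splits(c(3, 1, 2)), c(1.5, 2.5))
})

test_that("split criterion matches hand-evaluated weighted impurities", {
  expect_equal(split_criterion(c(1, 2, 3, 4), c(0, 0, 1, 1), 2.5), 0)
  expect_equal(split_criterion(c(1, 2, 3, 4), c(0, 1, 0, 1), 2.5), 0.5)
  expect_equal(split_criterion(c(1, 2, 3, 4, 5, 6), c(0, 0, 0, 1, 0, 1), 3.5),
               2 / 9)
  expect_equal(split_criterion(c(1, 2, 3, 4, 5, 6), c(0, 0, 0, 1, 0, 1), 3.5,
                               criterion = "unweighted-sum"),
               4 / 9)
  expect_error(split_criterion(c(1, 2, 3), c(0, 1, 1), 0.5),
               class = "besplit_validation_error")
  expect_error(split_criterion(c(1, 2, 3), c(0, 1), 1.5),
               class = "besplit_validation_error")
})

test_that("best_split returns the argmin with smallest-v tie-break", {
  r <- best_split(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$split_value, 2.5)
  expect_equal(r$gini_at_split, 0)
  expect_equal(c(r$n_below, r$n_above), c(2L, 2L))
  expect_equal(c(r$prob_below, r$prob_above), c(0, 1))
  expect_false(r$degenerate)

  # candidates {1.5, 2.5, 3.5, 4.5} give {0.3, 7/15, 4/15, 0.4}
  r <- best_split(c(1, 2, 3, 4, 5), c(0, 1, 0, 1, 1))
  expect_equal(r$split_value, 3.5)
  expect_equal(r$gini_at_split, 4 / 15)
  expect_equal(r$candidates_evaluated, 4L)

  # symmetric instance: both outer candidates tie; smallest v must win
  r <- best_split(c(1, 2, 3, 4), c(1, 0, 0, 1))
  expect_equal(r$split_value, 1.5)
})

test_that("degenerate inputs are reported, not fabricated", {
  r <- best_split(c(1, 2, 3, 4), c(0, 0, 0, 0))
  expect_true(r$degenerate)
  expect_equal(r$split_value, 2.5)  # median candidate
  expect_equal(c(r$n_below, r$n_above), c(2L, 2L))
  expect_equal(r$candidates_evaluated, 0L)

  r <- best_split(c(5, 5, 5), c(0, 1, 1))
  expect_true(r$degenerate)
  expect_equal(r$split_value, 5)
  expect_equal(r$n_below, 3L)

  expect_error(best_split(3, 1), class = "besplit_validation_error")
  expect_error(best_split(c(1, 2), c(0, 1, 1)), class = "besplit_validation_error")
  expect_error(best_split(c(-1, 2), c(0, 1)), class = "besplit_validation_error")
})

test_that("probabilities use AE counts and may exceed subject ratios", {
  r <- best_split(c(1, 2, 3, 4), c(0, 0, 1, 1), ae_counts = c(0, 0, 2, 3))
  expect_equal(r$ae_above, 5)
  expect_equal(r$prob_above, 2.5)
})

test_that("vectorized search agrees with the brute-force oracle", {
  set.seed(401)
  for (i in 1:100) {
    inst <- random_split_instance()
    got <- best_split(inst$values, inst$flags)
    want <- oracle_best_split(inst$values, inst$flags)
    expect_equal(got$split_value, want$split_value)
    expect_equal(got$gini_at_split, want$gini, tolerance = 1e-12)
  }
})

test_that("the chosen split index is invariant under monotone maps", {
  set.seed(402)
  maps <- list(function(x) x^2, function(x) 7 * x + 2, exp, log1p)
  for (i in 1:25) {
    inst <- random_split_instance()
    base <- best_split(inst$values, inst$flags)
    for (g in maps) {
      tr <- best_split(g(inst$values), inst$flags)
      expect_equal(tr$n_below, base$n_below)
      expect_equal(tr$ae_below, base$ae_below)
      # the split value maps into the image of the same sorted gap
      below <- sort(g(inst$values))[tr$n_below]
      above <- sort(g(inst$values))[tr$n_below + 1]
      expect_true(tr$split_value > below && tr$split_value < above)
    }
  }
})

test_that("splits never increase impurity and conserve counts", {
  set.seed(403)
  for (i in 1:50) {
    inst <- random_split_instance()
    counts <- inst$flags * sample(1:3, length(inst$flags), replace = TRUE)
    r <- best_split(inst$values, inst$flags, counts)
    root <- node_gini(c(sum(inst$flags), sum(!inst$flags)))
    expect_lte(r$gini_at_split, root + 1e-12)
    expect_equal(r$n_below + r$n_above, length(inst$values))
    expect_equal(r$ae_below + r$ae_above, sum(counts))
  }
})

test_that("study_splits processes PK studies only and is deterministic", {
  ds <- tiny_dataset()
  res <- study_splits(ds, "cmax")
  expect_equal(nrow(res), 1)
  expect_equal(res$study_id, "A")
  expect_equal(attr(res, "skipped"), "B")

  cfg <- synthetic_config(4, 30, p_below = 0.1, p_above = 0.5, seed = 5L)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_equal(as.data.frame(study_splits(d1, "auc")),
               as.data.frame(study_splits(d2, "auc")))
})
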