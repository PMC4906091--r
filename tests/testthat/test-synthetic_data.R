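test_that("config validation rejects non-monotone or degenerate settings", {
  expect_error(synthetic_config(5, 10, p_below = 0.4, p_above = 0.2),
               class = "besplit_validation_error")
  expect_error(synthetic_config(5, 10, pk_sigma = 0),
               class = "besplit_validation_error")
  expect_error(synthetic_config(0, 10), class = "besplit_validation_error")
  expect_error(synthetic_config(5, 10, subgroup_weights = c(oddly = 1)),
               class = "besplit_validation_error")
  expect_error(synthetic_config(5, 10, pk_studies = 9),
               class = "besplit_validation_error")
})

test_that("zero AE probability yields an event-free dataset", {
  cfg <- synthetic_config(3, 15, p_below = 0, p_above = 0, seed = 2L)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds$adverse_events), 0)
  expect_true(all(ds$subjects$ae_count == 0))
})

test_that("generation is deterministic down to CSV bytes", {
  cfg <- synthetic_config(4, 12, p_below = 0.2, p_above = 0.5, seed = 14L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(generate_dataset(cfg), d1)
  write_dataset(generate_dataset(cfg), d2)
  for (f in c("studies.csv", "subjects.csv", "adverse_events.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("per-study child streams shield earlier studies from later ones", {
  small <- generate_dataset(synthetic_config(3, 10, p_below = 0.1,
                                             p_above = 0.3, seed = 8L))
  large <- generate_dataset(synthetic_config(6, 10, p_below = 0.1,
                                             p_above = 0.3, seed = 8L))
  first3 <- large$subjects[large$subjects$study_id %in%
                             sprintf("S%04d", 1:3), ]
  expect_equal(as.data.frame(first3), as.data.frame(small$subjects))
})

test_that("the AE rate above the threshold matches the configured probability", {
  cfg <- synthetic_config(1, 20000, p_below = 0.1, p_above = 0.4,
                          threshold_theta = 100, seed = 77L)
  ds <- generate_dataset(cfg)
  above <- ds$subjects$cmax_mean > 100
  rate <- mean(ds$subjects$ae_flag[above])
  se <- sqrt(0.4 * 0.6 / sum(above))
  expect_lt(abs(rate - 0.4), 3 * se)
  rate_b <- mean(ds$subjects$ae_flag[!above])
  se_b <- sqrt(0.1 * 0.9 / sum(!above))
  expect_lt(abs(rate_b - 0.1), 3 * se_b)
})

test_that("per-study log-Cmax means stay within sampling error of pk_mu", {
  cfg <- synthetic_config(10, 200, pk_mu = log(80), pk_sigma = 0.3,
                          p_below = 0.1, p_above = 0.2, seed = 6L)
  ds <- generate_dataset(cfg)
  for (sid in unique(ds$subjects$study_id)) {
    m <- mean(log(ds$subjects$cmax_mean[ds$subjects$study_id == sid]))
    expect_lt(abs(m - log(80)), 4 * 0.3 / sqrt(200) + 0.02)
  }
})

test_that("poisson count model produces multi-event subjects at high rates", {
  cfg <- synthetic_config(1, 2000, p_below = 0.8, p_above = 0.9,
                          count_model = "poisson", seed = 13L)
  ds <- generate_dataset(cfg)
  expect_gt(max(ds$subjects$ae_count), 1)
  expect_equal(sum(ds$subjects$ae_count), nrow(ds$adverse_events))
})

test_that("scenario presets encode the documented study conditions", {
  p <- scenario_presets()
  expect_named(p, c("null", "step", "paper_like"))
  expect_equal(p$null$p_below, p$null$p_above)
  expect_gte(p$null$n_studies, 200)
  expect_equal(p$step$threshold_theta, 100)
  expect_equal(c(p$step$p_below, p$step$p_above), c(0.1, 0.4))
  expect_equal(p$paper_like$n_studies, 261L)
  expect_equal(p$paper_like$pk_studies, 63L)
  ds <- generate_dataset(p$paper_like)
  expect_equal(nrow(ds$studies), 261)
  expect_equal(sum(ds$studies$has_pk), 63)

  # one step replicate recovers the threshold
  su <- generate_dataset(p$step)$subjects
  sp <- best_split(su$cmax_mean, su$ae_flag, su$ae_count)
  expect_gt(sp$split_value, 95)
  expect_lt(sp$split_value, 105)
})
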