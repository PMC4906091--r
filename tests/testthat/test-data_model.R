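test_that("derived fields are computed on construction", {
  ds <- tiny_dataset()
  expect_equal(ds$subjects$ae_count, c(0L, 0L, 2L, 1L, 0L))
  expect_equal(ds$subjects$ae_flag, c(0L, 0L, 1L, 1L, 0L))
  expect_equal(ds$subjects$cmax_mean[1:3], c(11, 19, 29))
  expect_equal(ds$studies$has_pk, c(TRUE, FALSE))
})

test_that("referential and validation errors are raised with offending details", {
  ds <- tiny_dataset()

  bad <- ds
  bad$subjects$study_id[4] <- "ZZZ"
  expect_error(be_dataset(bad$studies, bad$subjects, bad$adverse_events),
               class = "besplit_integrity_error")

  bad <- ds
  bad$subjects$cmax_test[1] <- 0
  expect_error(be_dataset(bad$studies, bad$subjects, bad$adverse_events),
               "cmax_test", class = "besplit_validation_error")

  bad <- ds
  bad$subjects$cmax_ref[1] <- NA
  expect_error(be_dataset(bad$studies, bad$subjects, bad$adverse_events),
               class = "besplit_validation_error")

  bad <- ds
  bad$adverse_events$period[1] <- "V"
  expect_error(be_dataset(bad$studies, bad$subjects, bad$adverse_events),
               class = "besplit_validation_error")

  bad <- ds
  bad$studies$atc_subgroup[1] <- "something else"
  expect_error(be_dataset(bad$studies, bad$subjects, bad$adverse_events),
               "something else", class = "besplit_validation_error")

  bad <- ds
  bad$studies$n_subjects[1] <- 5L
  expect_error(be_dataset(bad$studies, bad$subjects, bad$adverse_events),
               class = "besplit_integrity_error")
})

test_that("CSV round trip is the identity on valid datasets", {
  dir <- withr::local_tempdir()
  ds <- tiny_dataset()
  paths <- write_dataset(ds, dir)
  back <- read_dataset(paths[["studies"]], paths[["subjects"]],
                       paths[["adverse_events"]])
  expect_equal(as.data.frame(back$studies), as.data.frame(ds$studies))
  expect_equal(as.data.frame(back$subjects), as.data.frame(ds$subjects))
  expect_equal(as.data.frame(back$adverse_events),
               as.data.frame(ds$adverse_events))
})

test_that("round trip preserves a 63-study simulated database", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(n_studies = 63, subjects_per_study = 8,
                          p_below = 0.1, p_above = 0.3, seed = 11L)
  ds <- generate_dataset(cfg)
  paths <- write_dataset(ds, dir)
  back <- read_dataset(paths[["studies"]], paths[["subjects"]],
                       paths[["adverse_events"]])
  for (part in c("studies", "subjects", "adverse_events")) {
    expect_equal(as.data.frame(back[[part]]), as.data.frame(ds[[part]]),
                 tolerance = 1e-12)
  }
})

test_that("an empty adverse-event table writes a header-only CSV", {
  dir <- withr::local_tempdir()
  ds <- tiny_dataset()
  ds2 <- be_dataset(ds$studies, ds$subjects, ds$adverse_events[0, ])
  paths <- write_dataset(ds2, dir)
  lines <- readLines(paths[["adverse_events"]])
  expect_length(lines, 1)
  expect_match(lines, "^study_id,")
})

test_that("missing columns in input CSVs name the column", {
  dir <- withr::local_tempdir()
  paths <- write_dataset(tiny_dataset(), dir)
  st <- readr::read_csv(paths[["studies"]], show_col_types = FALSE)
  st$atc_subgroup <- NULL
  readr::write_csv(st, paths[["studies"]])
  expect_error(read_dataset(paths[["studies"]], paths[["subjects"]],
                            paths[["adverse_events"]]),
               "atc_subgroup", class = "besplit_schema_error")
})

test_that("unit columns are harmonized on read", {
  dir <- withr::local_tempdir()
  paths <- write_dataset(tiny_dataset(), dir)
  su <- readr::read_csv(paths[["subjects"]], show_col_types = FALSE)
  pk <- !is.na(su$cmax_test)
  su$cmax_test[pk] <- su$cmax_test[pk] / 1000
  su$cmax_ref[pk] <- su$cmax_ref[pk] / 1000
  su$cmax_unit[pk] <- "ug/mL"
  readr::write_csv(su, paths[["subjects"]])
  back <- read_dataset(paths[["studies"]], paths[["subjects"]],
                       paths[["adverse_events"]])
  expect_equal(back$subjects$cmax_mean, tiny_dataset()$subjects$cmax_mean)
})

test_that("ae_count conservation holds across datasets", {
  for (ds in list(tiny_dataset(),
                  generate_dataset(synthetic_config(5, 20, p_below = 0.2,
                                                    p_above = 0.4, seed = 3L)))) {
    expect_equal(sum(ds$subjects$ae_count), nrow(ds$adverse_events))
  }
})
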