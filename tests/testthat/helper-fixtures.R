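# Shared builders for the tests. The reference fixture is expensive enough
# to build once per run.

cached_fixture <- local({
  env <- new.env()
  function() {
    if (is.null(env$fx)) env$fx <- paper_fixture()
    env$fx
  }
})

# A small, fully in-code dataset: two studies, one with PK.
tiny_dataset <- function() {
  studies <- tibble::tibble(
    study_id = c("A", "B"),
    api_name = c("api1", "api2"),
    atc_subgroup = c("nervous system", "cardiovascular system"),
    n_periods = c(2L, 2L),
    n_subjects = c(3L, 2L),
    year = c(2010L, NA_integer_)
  )
  subjects <- tibble::tibble(
    study_id = c("A", "A", "A", "B", "B"),
    subject_id = c("s1", "s2", "s3", "s1", "s2"),
    cmax_test = c(10, 20, 30, NA, NA),
    cmax_ref = c(12, 18, 28, NA, NA),
    auc_test = c(100, 200, 300, NA, NA),
    auc_ref = c(110, 190, 290, NA, NA)
  )
  events <- tibble::tibble(
    study_id = c("A", "A", "B"),
    subject_id = c("s3", "s3", "s1"),
    ae_type = c("headache", "nausea", "dizziness"),
    period = c("I", "II", "I"),
    serious = c(FALSE, FALSE, FALSE),
    drug_arm = c("test", "reference", "unknown")
  )
  be_dataset(studies, subjects, events)
}

# Independent brute-force split search: naive loops, no shared helpers with
# the package's vectorized path. Ties resolved towards the smallest
# threshold, treating criterion values within 1e-12 as equal.
oracle_best_split <- function(values, flags) {
  n <- length(values)
  u <- sort(unique(values))
  stopifnot(length(u) >= 2, length(unique(flags)) == 2)
  impurity <- function(f) {
    p1 <- sum(f == 1) / length(f)
    1 - p1^2 - (1 - p1)^2
  }
  best_v <- NA_real_
  best_g <- Inf
  for (i in seq_len(length(u) - 1)) {
    v <- (u[i] + u[i + 1]) / 2
    left <- flags[values <= v]
    right <- flags[values > v]
    g <- (length(left) / n) * impurity(left) + (length(right) / n) * impurity(right)
    if (g < best_g - 1e-12) {
      best_g <- g
      best_v <- v
    }
  }
  list(split_value = best_v, gini = best_g)
}

random_split_instance <- function() {
  n <- sample(4:30, 1)
  # integer-ish values so duplicate values and criterion ties actually occur
  values <- sample(1:12, n, replace = TRUE)
  flags <- sample(0:1, n, replace = TRUE)
  if (length(unique(values)) < 2) values[1] <- values[1] + 13L
  if (length(unique(flags)) < 2) flags[1] <- 1L - flags[1]
  list(values = values, flags = flags)
}
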