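#' Gini impurity of a single node
#'
#' For class counts \eqn{c_j} with total \eqn{N}, the impurity is
#' \eqn{1 - \sum_j (c_j/N)^2}. For the binary adverse-event class
#' (exists / not exists) the range is \[0, 0.5\]: 0 for a pure node, 0.5 for
#' a balanced one.
#'
#' @param class_counts nonnegative numeric vector of per-class counts,
#'   total > 0.
#' @return The impurity, a scalar in \[0, 1).
#' @export
#' @examples
#' node_gini(c(0, 10))  # pure node: 0
#' node_gini(c(5, 5))   # maximal binary impurity: 0.5
node_gini <- function(class_counts) {
  if (any(class_counts < 0)) {
    stop_besplit("class counts must be nonnegative", "besplit_validation_error")
  }
  total <- sum(class_counts)
  if (total <= 0) {
    stop_besplit("node impurity undefined for an empty node", "besplit_validation_error")
  }
  1 - sum((class_counts / total)^2)
}

#' Candidate split positions for a continuous covariate
#'
#' Midpoints between adjacent *distinct* sorted values, in ascending order.
#' With fewer than two distinct values no split is possible and the result is
#' empty. Because candidates sit strictly between distinct data values, a
#' candidate can never coincide with an observation, so the side convention
#' (below = value <= v) is unambiguous on the data that produced it.
#'
#' @param values numeric vector, `n >= 1`.
#' @return Ascending numeric vector of candidate thresholds.
#' @export
#' @examples
#' candidate_splits(c(1, 2, 3))  # 1.5 2.5
#' candidate_splits(c(2, 2, 4))  # 3
candidate_splits <- function(values) {
  u <- sort(unique(values))
  if (length(u) < 2) return(numeric(0))
  (u[-length(u)] + u[-1]) / 2
}

#' Split criterion at a given threshold
#'
#' Weighted average of the child Gini impurities:
#' \eqn{(n_L/n)\,G(L) + (n_R/n)\,G(R)} with \eqn{L = \{x \le v\}},
#' \eqn{R = \{x > v\}}. The `"unweighted-sum"` variant returns
#' \eqn{G(L) + G(R)} and is provided for sensitivity analysis only.
#'
#' @param values numeric covariate vector.
#' @param flags binary class labels (0/1), same length as `values`.
#' @param v threshold, strictly between `min(values)` and `max(values)`.
#' @param criterion `"weighted"` (default) or `"unweighted-sum"`.
#' @return The criterion value; in \[0, 0.5\] for the weighted binary case.
#' @export
#' @examples
#' split_criterion(c(1, 2, 3, 4), c(0, 0, 1, 1), 2.5)  # perfect separation: 0
split_criterion <- function(values, flags, v,
                            criterion = c("weighted", "unweighted-sum")) {
  criterion <- match.arg(criterion)
  if (length(values) != length(flags)) {
    stop_besplit("values and flags must have equal length", "besplit_validation_error")
  }
  if (!(v > min(values) && v < max(values))) {
    stop_besplit("threshold must lie strictly between min and max of values (no empty side)",
                 "besplit_validation_error")
  }
  left <- values <= v
  gl <- node_gini(c(sum(flags[left]), sum(!flags[left])))
  gr <- node_gini(c(sum(flags[!left]), sum(!flags[!left])))
  nl <- sum(left)
  n <- length(values)
  if (criterion == "weighted") {
    (nl / n) * gl + ((n - nl) / n) * gr
  } else {
    gl + gr
  }
}

# Criterion evaluated at every candidate in one vectorized sweep.
# Candidates are ascending, so which.min realizes the smallest-v tie-break.
criterion_profile <- function(values, flags, criterion) {
  ord <- order(values)
  v_sorted <- values[ord]
  f_sorted <- flags[ord]
  n <- length(values)
  total_f <- sum(f_sorted)
  cum_f <- cumsum(f_sorted)
  # candidate after sorted position i exists iff v_sorted[i] != v_sorted[i+1]
  boundary <- which(v_sorted[-n] != v_sorted[-1])
  if (length(boundary) == 0) return(NULL)
  nl <- boundary
  fl <- cum_f[boundary]
  nr <- n - nl
  fr <- total_f - fl
  gl <- 1 - (fl / nl)^2 - ((nl - fl) / nl)^2
  gr <- 1 - (fr / nr)^2 - ((nr - fr) / nr)^2
  crit <- if (criterion == "weighted") (nl / n) * gl + (nr / n) * gr else gl + gr
  list(
    candidates = (v_sorted[boundary] + v_sorted[boundary + 1]) / 2,
    criterion = crit,
    n_below = nl
  )
}

#' Exhaustive best-split search on subject-mean PK values
#'
#' Sorts the values, forms candidate thresholds at midpoints between adjacent
#' distinct values, evaluates the split criterion at every candidate and
#' returns the minimizer; ties are broken towards the smallest threshold.
#' When all class labels agree or fewer than two distinct values exist, no
#' informative split exists: the result is marked `degenerate` and the split
#' is placed at the median candidate (or the single value), with both-side
#' counts still reported so pooling remains well defined.
#'
#' Class impurity is computed on the binary flag; the reported probabilities
#' `prob_below`/`prob_above` divide adverse-event *counts* by subject counts,
#' so they may exceed 1 when subjects experience multiple events; they are
#' deliberately not clamped.
#'
#' @param values positive numeric vector of subject-mean PK values, `n >= 2`.
#' @param flags binary class labels (1 iff the subject had any adverse
#'   event).
#' @param ae_counts nonnegative per-subject adverse-event counts; defaults to
#'   `flags`.
#' @param criterion see [split_criterion()].
#' @return A one-row [tibble::tibble] (class `be_split`) with columns
#'   `split_value`, `gini_at_split`, `n_below`, `n_above`, `ae_below`,
#'   `ae_above`, `prob_below`, `prob_above`, `degenerate`,
#'   `candidates_evaluated`.
#' @export
#' @examples
#' best_split(c(1, 2, 3, 4), c(0, 0, 1, 1))
best_split <- function(values, flags, ae_counts = flags,
                       criterion = c("weighted", "unweighted-sum")) {
  criterion <- match.arg(criterion)
  n <- length(values)
  if (n < 2) {
    stop_besplit("best_split requires at least 2 observations", "besplit_validation_error")
  }
  if (length(flags) != n || length(ae_counts) != n) {
    stop_besplit("values, flags and ae_counts must have equal length",
                 "besplit_validation_error")
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop_besplit("PK values must be finite and strictly positive",
                 "besplit_validation_error")
  }
  if (!all(flags %in% c(0, 1))) {
    stop_besplit("flags must be binary (0/1)", "besplit_validation_error")
  }

  cand <- candidate_splits(values)
  single_class <- length(unique(flags)) < 2
  degenerate <- single_class || length(cand) == 0

  if (degenerate) {
    v <- if (length(cand) == 0) values[1] else cand[ceiling(length(cand) / 2)]
    evaluated <- 0L
    g <- 0
    if (!single_class) g <- node_gini(c(sum(flags), n - sum(flags)))
  } else {
    prof <- criterion_profile(values, flags, criterion)
    # smallest-v tie-break; criterion values within 1e-12 count as tied so
    # floating-point noise cannot flip the winner between exact ties
    best <- which(prof$criterion <= min(prof$criterion) + 1e-12)[1]
    v <- prof$candidates[best]
    g <- prof$criterion[best]
    evaluated <- length(prof$candidates)
  }

  below <- values <= v
  res <- tibble::tibble(
    split_value = v,
    gini_at_split = g,
    n_below = sum(below),
    n_above = sum(!below),
    ae_below = sum(ae_counts[below]),
    ae_above = sum(ae_counts[!below]),
    degenerate = degenerate,
    candidates_evaluated = evaluated
  )
  res$prob_below <- ifelse(res$n_below > 0, res$ae_below / res$n_below, NA_real_)
  res$prob_above <- ifelse(res$n_above > 0, res$ae_above / res$n_above, NA_real_)
  class(res) <- c("be_split", class(res))
  res
}

#' Per-study split points over a BE dataset
#'
#' Runs [best_split()] on the subject-mean values of the chosen PK parameter
#' for every study with complete PK data; studies without PK are skipped and
#' listed in the `"skipped"` attribute of the result.
#'
#' @param dataset a validated `be_dataset`.
#' @param parameter `"cmax"` or `"auc"`.
#' @param criterion see [split_criterion()].
#' @return A tibble with one row per PK-bearing study: `study_id`,
#'   `parameter`, then the [best_split()] columns. Attribute `skipped` holds
#'   the study ids without PK data.
#' @export
study_splits <- function(dataset, parameter = c("cmax", "auc"),
                         criterion = c("weighted", "unweighted-sum")) {
  parameter <- match_parameter(match.arg(parameter))
  criterion <- match.arg(criterion)
  col <- paste0(parameter, "_mean")

  pk_ids <- dataset$studies$study_id[dataset$studies$has_pk]
  skipped <- dataset$studies$study_id[!dataset$studies$has_pk]

  rows <- lapply(pk_ids, function(sid) {
    su <- dataset$subjects[dataset$subjects$study_id == sid, ]
    res <- best_split(su[[col]], su$ae_flag, su$ae_count, criterion = criterion)
    res$study_id <- sid
    res$parameter <- parameter
    res
  })
  out <- if (length(rows) == 0) {
    empty <- best_split(c(1, 2), c(0, 1))[0, ]
    empty$study_id <- character(0)
    empty$parameter <- character(0)
    empty
  } else {
    dplyr::bind_rows(rows)
  }
  out <- out[, c("study_id", "parameter", "split_value", "gini_at_split",
                 "n_below", "n_above", "ae_below", "ae_above",
                 "prob_below", "prob_above", "degenerate",
                 "candidates_evaluated")]
  attr(out, "skipped") <- skipped
  out
}
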