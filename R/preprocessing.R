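#' Default unit-conversion table for pharmacokinetic parameters
#'
#' Canonical units are ng/mL for Cmax and ng.h/mL for AUC. Each entry maps a
#' unit label to the multiplicative factor that converts a value in that unit
#' into the canonical unit. Unicode spellings (micro sign, middle dot) are
#' accepted as aliases of the ASCII labels.
#'
#' @return A named list with elements `cmax` and `auc`, each a named numeric
#'   vector of conversion factors.
#' @export
default_units <- function() {
  list(
    cmax = stats::setNames(
      c(1, 1000, 1000, 1000),
      c("ng/mL", "ug/mL", "\u00b5g/mL", "mg/L")
    ),
    auc = stats::setNames(
      c(1, 1, 1000, 1000, 1000, 1000),
      c("ng.h/mL", "ng\u00b7h/mL", "ug.h/mL", "\u00b5g\u00b7h/mL",
        "mg.h/L", "mg\u00b7h/L")
    )
  )
}

canonical_unit <- function(parameter) {
  switch(match_parameter(parameter), cmax = "ng/mL", auc = "ng.h/mL")
}

match_parameter <- function(parameter) {
  p <- tolower(as.character(parameter))
  if (!p %in% c("cmax", "auc")) {
    stop_besplit(sprintf("unknown PK parameter '%s' (expected 'cmax' or 'auc')", parameter),
                 "besplit_validation_error")
  }
  p
}

#' Convert PK values into the canonical unit
#'
#' @param value numeric vector of measurements.
#' @param unit unit label(s), recycled against `value`.
#' @param parameter `"cmax"` or `"auc"`; selects which unit table applies.
#' @param units unit table as returned by [default_units()]; may be extended
#'   with additional labels, all factors strictly positive.
#' @return `value` multiplied into ng/mL (Cmax) or ng.h/mL (AUC).
#' @export
#' @examples
#' harmonize_units(1, "ug/mL", "cmax")   # 1000 ng/mL
#' harmonize_units(2, "mg.h/L", "auc")   # 2000 ng.h/mL
harmonize_units <- function(value, unit, parameter, units = default_units()) {
  p <- match_parameter(parameter)
  table <- units[[p]]
  if (any(table <= 0) || is.null(names(table))) {
    stop_besplit("unit table factors must be named and strictly positive",
                 "besplit_validation_error")
  }
  unit <- rep_len(as.character(unit), length(value))
  idx <- match(unit, names(table))
  bad <- !is.na(value) & is.na(idx)
  if (any(bad)) {
    stop_besplit(sprintf("unknown %s unit label(s): %s", p,
                         paste(unique(unit[bad]), collapse = ", ")),
                 "besplit_conversion_error")
  }
  out <- value * unname(table[idx])
  out[is.na(value)] <- NA_real_
  out
}

#' Natural-log transform of strictly positive values
#'
#' @param values numeric vector, all strictly positive.
#' @return `log(values)`.
#' @export
log_transform <- function(values) {
  bad <- which(!is.na(values) & values <= 0)
  if (length(bad) > 0) {
    stop_besplit(sprintf("log transform requires strictly positive values; offending indices: %s",
                         paste(utils::head(bad, 10), collapse = ", ")),
                 "besplit_domain_error")
  }
  log(values)
}

#' Normality check with estimated parameters
#'
#' Lilliefors-corrected Kolmogorov-Smirnov test of composite normality (mean
#' and standard deviation estimated from the sample), the defensible reading
#' of a KS normality screen applied to observed PK variables.
#'
#' @param values numeric vector, `n >= 5`, non-degenerate scale.
#' @param alpha significance level in (0, 1); default 0.05.
#' @return A list with `statistic`, `p_value` and `normal`
#'   (`TRUE` iff `p_value > alpha`).
#' @export
normality_check <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 5) {
    stop_besplit("normality check requires at least 5 observations",
                 "besplit_validation_error")
  }
  if (!(alpha > 0 && alpha < 1)) {
    stop_besplit("alpha must lie in (0, 1)", "besplit_validation_error")
  }
  if (stats::sd(values) == 0) {
    stop_besplit("normality check undefined for a constant sample (estimated scale is zero)",
                 "besplit_domain_error")
  }
  ks <- nortest::lillie.test(values)
  list(
    statistic = unname(ks$statistic),
    p_value = unname(ks$p.value),
    normal = unname(ks$p.value) > alpha
  )
}

#' Paired comparison of test and reference PK values
#'
#' Paired t-test on natural-log-transformed test/reference pairs, the standard
#' comparison of the two arms of a crossover BE design after the variance-
#' stabilising log transform.
#'
#' @param test_values,ref_values strictly positive numeric vectors of equal
#'   length (>= 2), paired by subject.
#' @param alpha significance level; default 0.05.
#' @param parameter optional label (`"cmax"` or `"auc"`) carried into the
#'   result for bookkeeping.
#' @return A one-row [tibble::tibble] with columns `parameter`, `statistic`,
#'   `p_value`, `n`, `mean_log_difference` (test minus reference on the log
#'   scale) and `significant`.
#' @export
paired_comparison <- function(test_values, ref_values, alpha = 0.05,
                              parameter = NA_character_) {
  if (length(test_values) != length(ref_values)) {
    stop_besplit("test and reference vectors must have equal length",
                 "besplit_validation_error")
  }
  keep <- !is.na(test_values) & !is.na(ref_values)
  test_values <- test_values[keep]
  ref_values <- ref_values[keep]
  if (length(test_values) < 2) {
    stop_besplit("paired comparison requires at least 2 complete pairs",
                 "besplit_validation_error")
  }
  d <- log_transform(test_values) - log_transform(ref_values)
  stderr_d <- stats::sd(d) / sqrt(length(d))
  # zero-variance limit (same degeneracy threshold t.test applies):
  # t is 0/0 for all-equal pairs, +/-Inf for a constant nonzero ratio
  if (stderr_d < 10 * .Machine$double.eps * max(1, abs(mean(d)))) {
    near_zero <- abs(mean(d)) <= stderr_d
    stat <- if (near_zero) 0 else sign(mean(d)) * Inf
    p <- if (near_zero) 1 else 0
  } else {
    tt <- stats::t.test(d)
    stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  tibble::tibble(
    parameter = if (is.na(parameter)) NA_character_ else match_parameter(parameter),
    statistic = stat,
    p_value = p,
    n = length(d),
    mean_log_difference = mean(d),
    significant = p < alpha
  )
}

#' Flag extreme values on the log scale
#'
#' Indices of observations lying more than 3 interquartile ranges beyond the
#' quartiles. Flagging only: no removal is performed, matching a pipeline in
#' which extreme raw values are inspected but the log scale tames them.
#'
#' @param log_values numeric vector of already log-transformed, finite values.
#' @return Integer indices of flagged observations (possibly empty).
#' @export
flag_extremes <- function(log_values) {
  if (any(!is.finite(log_values))) {
    stop_besplit("flag_extremes requires finite values", "besplit_validation_error")
  }
  q <- stats::quantile(log_values, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  which(log_values < q[1] - 3 * iqr | log_values > q[2] + 3 * iqr)
}
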