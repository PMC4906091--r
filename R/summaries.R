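#' Round half away from zero
#'
#' Commercial rounding used for all reported frequencies and probabilities
#' (R's own `round()` rounds half to even). One decimal for percentages, two
#' for per-study/per-volunteer frequencies, three for probabilities.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Overall adverse-event frequencies
#'
#' @param dataset a validated `be_dataset` with at least one study and one
#'   subject.
#' @return List with `per_study` (total events / number of studies, 2 dp)
#'   and `per_volunteer` (total events / total volunteers, 2 dp).
#' @export
overall_frequencies <- function(dataset) {
  n_studies <- nrow(dataset$studies)
  n_vol <- nrow(dataset$subjects)
  if (n_studies == 0 || n_vol == 0) {
    stop_besplit("overall frequencies undefined for an empty dataset",
                 "besplit_validation_error")
  }
  n_ev <- nrow(dataset$adverse_events)
  list(
    per_study = round_half_away(n_ev / n_studies, 2),
    per_volunteer = round_half_away(n_ev / n_vol, 2)
  )
}

#' Adverse-event frequency by ATC drug subgroup
#'
#' One row per ATC level-1 subgroup present in the dataset plus a total row:
#' number of studies, volunteers and adverse events, and the event frequency
#' per volunteer as a percentage (1 dp).
#'
#' @param dataset a validated `be_dataset`.
#' @return A tibble with columns `atc_subgroup`, `n_studies`,
#'   `n_volunteers`, `n_events`, `frequency_percent`.
#' @export
subgroup_frequency_table <- function(dataset) {
  st <- dataset$studies
  groups <- atc_subgroups()[atc_subgroups() %in% st$atc_subgroup]
  subj_group <- st$atc_subgroup[match(dataset$subjects$study_id, st$study_id)]
  ev_group <- st$atc_subgroup[match(dataset$adverse_events$study_id, st$study_id)]
  rows <- tibble::tibble(
    atc_subgroup = groups,
    n_studies = as.integer(table(factor(st$atc_subgroup, levels = groups))),
    n_volunteers = as.integer(table(factor(subj_group, levels = groups))),
    n_events = as.integer(table(factor(ev_group, levels = groups)))
  )
  total <- tibble::tibble(
    atc_subgroup = "total",
    n_studies = sum(rows$n_studies),
    n_volunteers = sum(rows$n_volunteers),
    n_events = sum(rows$n_events)
  )
  out <- dplyr::bind_rows(rows, total)
  out$frequency_percent <- round_half_away(100 * out$n_events / out$n_volunteers, 1)
  out
}

#' Adverse-event types by crossover period
#'
#' Rows for the `top_k` most frequent adverse-event types (ties broken by
#' label order), a collapsed "other adverse events" row, and a total row;
#' columns give per-period counts, the type total and its share of all
#' events as a percentage (1 dp).
#'
#' @param dataset a validated `be_dataset`.
#' @param top_k number of named types to keep; default 5.
#' @return A tibble with columns `ae_type`, one column per period label,
#'   `total`, `share_percent`.
#' @export
ae_type_table <- function(dataset, top_k = 5) {
  if (top_k < 1) {
    stop_besplit("top_k must be >= 1", "besplit_validation_error")
  }
  ev <- dataset$adverse_events
  totals <- sort(table(ev$ae_type), decreasing = TRUE)
  # stable tie-break: order by count desc, then label
  ord <- order(-as.integer(totals), names(totals))
  totals <- totals[ord]
  top <- names(totals)[seq_len(min(top_k, length(totals)))]

  type_grp <- ifelse(ev$ae_type %in% top, ev$ae_type, "other adverse events")
  # the remainder row merges into an identically named top type if one exists
  levels_out <- unique(c(top, if (any(!ev$ae_type %in% top)) "other adverse events"))
  tab <- table(factor(type_grp, levels = levels_out),
               factor(ev$period, levels = ae_periods()))
  out <- tibble::as_tibble(as.data.frame.matrix(tab), rownames = "ae_type")
  total_row <- c(list(ae_type = "total"), as.list(colSums(tab)))
  out <- dplyr::bind_rows(out, tibble::as_tibble(total_row))
  out$total <- rowSums(out[, ae_periods()])
  out$share_percent <- round_half_away(100 * out$total / nrow(ev), 1)
  out
}

#' Pool per-study split results into above/below contingency summaries
#'
#' Sums the below/above adverse-event and subject counts of per-study split
#' results ([study_splits()]) over all studies, or within each ATC subgroup,
#' and reports the side probabilities (events / subjects, 3 dp) together
#' with which side carries the higher probability.
#'
#' @param split_results tibble from [study_splits()].
#' @param dataset the `be_dataset` the splits were computed on (supplies the
#'   subgroup of each study).
#' @param by_subgroup if `TRUE`, one stratum per ATC subgroup present among
#'   the split studies; otherwise a single overall stratum.
#' @return A tibble with columns `stratum`, `parameter`, `ae_below`,
#'   `ae_above`, `n_below`, `n_above`, `prob_below`, `prob_above`,
#'   `higher_side` (`"below"`, `"above"` or `"tie"`, compared after
#'   rounding).
#' @export
pool_splits <- function(split_results, dataset, by_subgroup = FALSE) {
  if (nrow(split_results) == 0) {
    stop_besplit("no split results to pool", "besplit_validation_error")
  }
  parameter <- unique(split_results$parameter)
  if (length(parameter) != 1) {
    stop_besplit("split results mix PK parameters; pool one parameter at a time",
                 "besplit_validation_error")
  }
  sr <- split_results
  sr$stratum <- if (by_subgroup) {
    dataset$studies$atc_subgroup[match(sr$study_id, dataset$studies$study_id)]
  } else {
    "overall"
  }
  out <- dplyr::bind_rows(lapply(split(sr, sr$stratum), function(d) {
    tibble::tibble(
      stratum = d$stratum[1],
      ae_below = sum(d$ae_below),
      ae_above = sum(d$ae_above),
      n_below = sum(d$n_below),
      n_above = sum(d$n_above)
    )
  }))
  if (by_subgroup) {
    out <- out[order(match(out$stratum, atc_subgroups())), ]
  }
  out$parameter <- parameter
  out$prob_below <- round_half_away(out$ae_below / out$n_below, 3)
  out$prob_above <- round_half_away(out$ae_above / out$n_above, 3)
  out$higher_side <- dplyr::case_when(
    out$prob_above > out$prob_below ~ "above",
    out$prob_above < out$prob_below ~ "below",
    TRUE ~ "tie"
  )
  out[, c("stratum", "parameter", "ae_below", "ae_above", "n_below",
          "n_above", "prob_below", "prob_above", "higher_side")]
}

#' Descriptive statistics of a numeric variable
#'
#' @param values numeric vector, `n >= 1`.
#' @return List with `mean`, `sd` (sample, n-1; 0 with `degenerate = TRUE`
#'   for a single observation), `min`, `max`, `n`, `degenerate`.
#' @export
describe <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    stop_besplit("describe requires at least one observation", "besplit_validation_error")
  }
  degenerate <- length(values) == 1
  list(
    mean = mean(values),
    sd = if (degenerate) 0 else stats::sd(values),
    min = min(values),
    max = max(values),
    n = length(values),
    degenerate = degenerate
  )
}
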