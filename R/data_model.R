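#' Closed vocabularies of the BE data model
#'
#' `atc_subgroups()` returns the eight ATC level-1 (anatomical main group)
#' labels a pooled BE database is stratified by; `ae_periods()` the crossover
#' period labels an adverse event can be attributed to, where
#' `"washout_or_predose"` collects events observed before dosing or during a
#' washout interval.
#'
#' @return Character vector of allowed labels.
#' @export
atc_subgroups <- function() {
  c(
    "cardiovascular system",
    "antiinfectives for systemic use",
    "musculo-skeletal system",
    "alimentary tract and metabolism",
    "nervous system",
    "respiratory system",
    "genito-urinary system and sex hormones",
    "antineoplastic and immunomodulating agents"
  )
}

#' @rdname atc_subgroups
#' @export
ae_periods <- function() {
  c("I", "II", "III", "IV", "washout_or_predose")
}

stop_besplit <- function(message, class) {
  stop(structure(
    class = c(class, "besplit_error", "error", "condition"),
    list(message = message, call = NULL)
  ))
}

studies_schema <- c("study_id", "api_name", "atc_subgroup", "n_periods",
                    "n_subjects", "year")
subjects_schema <- c("study_id", "subject_id", "cmax_test", "cmax_ref",
                     "cmax_unit", "auc_test", "auc_ref", "auc_unit")
events_schema <- c("study_id", "subject_id", "ae_type", "period", "serious",
                   "drug_arm")

#' Construct a validated BE dataset
#'
#' Assembles study, subject and adverse-event tables into a `be_dataset`,
#' computing the derived fields: per-subject arithmetic means of test and
#' reference PK values (`cmax_mean`, `auc_mean`), the adverse-event count and
#' binary class label (`ae_count`, `ae_flag`), and the per-study `has_pk`
#' indicator (all subjects carry complete Cmax and AUC values). PK inputs are
#' assumed to be in canonical units already; [read_dataset()] harmonizes
#' units before calling this constructor.
#'
#' @param studies data frame with columns `study_id`, `api_name`,
#'   `atc_subgroup`, `n_periods`, `n_subjects`, `year` (`year` may be `NA`).
#' @param subjects data frame with columns `study_id`, `subject_id`,
#'   `cmax_test`, `cmax_ref`, `auc_test`, `auc_ref` (canonical units; `NA`
#'   when unavailable).
#' @param adverse_events data frame with columns `study_id`, `subject_id`,
#'   `ae_type`, `period`, `serious`, `drug_arm`; may have zero rows.
#' @return An object of class `be_dataset`: a list with elements `studies`,
#'   `subjects`, `adverse_events` (tibbles).
#' @export
be_dataset <- function(studies, subjects, adverse_events) {
  studies <- tibble::as_tibble(studies)
  subjects <- tibble::as_tibble(subjects)
  adverse_events <- tibble::as_tibble(adverse_events)

  key <- paste(subjects$study_id, subjects$subject_id, sep = "\r")
  ev_key <- paste(adverse_events$study_id, adverse_events$subject_id, sep = "\r")
  ae_count <- as.integer(table(factor(ev_key, levels = key)))

  subjects$cmax_mean <- (subjects$cmax_test + subjects$cmax_ref) / 2
  subjects$auc_mean <- (subjects$auc_test + subjects$auc_ref) / 2
  subjects$ae_count <- ae_count
  subjects$ae_flag <- as.integer(ae_count > 0)

  pk_complete <- !is.na(subjects$cmax_test) & !is.na(subjects$cmax_ref) &
    !is.na(subjects$auc_test) & !is.na(subjects$auc_ref)
  pk_by_study <- tapply(pk_complete,
                        factor(subjects$study_id, levels = studies$study_id),
                        all)
  studies$has_pk <- as.vector(!is.na(pk_by_study) & as.logical(pk_by_study))

  ds <- structure(
    list(studies = studies, subjects = subjects, adverse_events = adverse_events),
    class = "be_dataset"
  )
  validate_dataset(ds)
}

#' Validate a BE dataset against its structural invariants
#'
#' Checks the closed vocabularies (`atc_subgroup`, `period`, `n_periods`),
#' positivity and pairing of PK values (test and reference present or absent
#' together per parameter), uniqueness of identifiers, referential integrity
#' of subjects and adverse events, agreement of per-study subject counts with
#' `n_subjects`, and conservation of adverse-event counts.
#'
#' @param dataset a `be_dataset`.
#' @return The dataset, invisibly, if valid; otherwise an error of class
#'   `besplit_validation_error` or `besplit_integrity_error`.
#' @export
validate_dataset <- function(dataset) {
  st <- dataset$studies
  su <- dataset$subjects
  ev <- dataset$adverse_events

  if (anyDuplicated(st$study_id)) {
    stop_besplit("duplicated study_id in studies table", "besplit_integrity_error")
  }
  if (!all(st$atc_subgroup %in% atc_subgroups())) {
    bad <- unique(st$atc_subgroup[!st$atc_subgroup %in% atc_subgroups()])
    stop_besplit(paste0("unknown atc_subgroup label(s): ", paste(bad, collapse = "; ")),
                 "besplit_validation_error")
  }
  if (!all(st$n_periods %in% c(2L, 3L, 4L))) {
    stop_besplit("n_periods must be 2, 3 or 4", "besplit_validation_error")
  }
  if (any(st$n_subjects < 1)) {
    stop_besplit("n_subjects must be >= 1 for every study", "besplit_validation_error")
  }

  key <- paste(su$study_id, su$subject_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop_besplit("duplicated (study_id, subject_id) in subjects table",
                 "besplit_integrity_error")
  }
  dangling <- unique(su$study_id[!su$study_id %in% st$study_id])
  if (length(dangling) > 0) {
    stop_besplit(paste0("subjects reference unknown study_id: ",
                        paste(dangling, collapse = ", ")),
                 "besplit_integrity_error")
  }
  for (col in c("cmax_test", "cmax_ref", "auc_test", "auc_ref")) {
    v <- su[[col]]
    if (any(!is.na(v) & v <= 0)) {
      stop_besplit(paste0("nonpositive PK value in column ", col),
                   "besplit_validation_error")
    }
  }
  if (any(is.na(su$cmax_test) != is.na(su$cmax_ref)) ||
      any(is.na(su$auc_test) != is.na(su$auc_ref))) {
    stop_besplit("test and reference PK values must be present or absent together",
                 "besplit_validation_error")
  }

  counts <- table(factor(su$study_id, levels = st$study_id))
  if (!all(as.integer(counts) == st$n_subjects)) {
    off <- st$study_id[as.integer(counts) != st$n_subjects]
    stop_besplit(paste0("per-study subject counts disagree with n_subjects for: ",
                        paste(utils::head(off, 10), collapse = ", ")),
                 "besplit_integrity_error")
  }

  if (nrow(ev) > 0) {
    ev_key <- paste(ev$study_id, ev$subject_id, sep = "\r")
    bad <- unique(ev_key[!ev_key %in% key])
    if (length(bad) > 0) {
      stop_besplit(paste0("adverse events reference unknown (study_id, subject_id): ",
                          paste(gsub("\r", "/", utils::head(bad, 10)), collapse = ", ")),
                   "besplit_integrity_error")
    }
    if (!all(ev$period %in% ae_periods())) {
      stop_besplit("adverse-event period outside {I, II, III, IV, washout_or_predose}",
                   "besplit_validation_error")
    }
    if (any(!nzchar(ev$ae_type))) {
      stop_besplit("ae_type must be nonempty", "besplit_validation_error")
    }
    if (!all(ev$drug_arm %in% c("test", "reference", "unknown"))) {
      stop_besplit("drug_arm must be one of test/reference/unknown",
                   "besplit_validation_error")
    }
  }

  if (!is.null(su$ae_count)) {
    recount <- as.integer(table(factor(
      paste(ev$study_id, ev$subject_id, sep = "\r"), levels = key)))
    if (!identical(recount, as.integer(su$ae_count))) {
      stop_besplit("per-subject ae_count does not equal the number of linked adverse events",
                   "besplit_integrity_error")
    }
  }
  invisible(dataset)
}

#' @export
print.be_dataset <- function(x, ...) {
  cat(sprintf("<be_dataset> %d studies (%d with PK), %d subjects, %d adverse events\n",
              nrow(x$studies), sum(x$studies$has_pk),
              nrow(x$subjects), nrow(x$adverse_events)))
  invisible(x)
}

read_checked <- function(path, schema, col_types) {
  if (!file.exists(path)) {
    stop_besplit(paste0("file not found: ", path), "besplit_io_error")
  }
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                                  progress = FALSE))
  missing <- setdiff(schema, header)
  if (length(missing) > 0) {
    stop_besplit(paste0("missing column(s) in ", basename(path), ": ",
                        paste(missing, collapse = ", ")),
                 "besplit_schema_error")
  }
  readr::read_csv(path, col_types = col_types, progress = FALSE)
}

#' Read a BE dataset from three CSV files
#'
#' Expects the schemas: `studies.csv` (`study_id, api_name, atc_subgroup,
#' n_periods, n_subjects, year`), `subjects.csv` (`study_id, subject_id,
#' cmax_test, cmax_ref, cmax_unit, auc_test, auc_ref, auc_unit`) and
#' `adverse_events.csv` (`study_id, subject_id, ae_type, period, serious,
#' drug_arm`). Empty PK cells mean the value is unavailable. PK values are
#' harmonized into canonical units (ng/mL, ng.h/mL) on read; an empty unit
#' cell next to a present value is taken as already canonical.
#'
#' @param studies_path,subjects_path,events_path paths to the three CSVs.
#' @param units unit table, see [default_units()].
#' @return A validated [be_dataset()].
#' @export
read_dataset <- function(studies_path, subjects_path, events_path,
                         units = default_units()) {
  studies <- read_checked(studies_path, studies_schema,
                          readr::cols(study_id = "c", api_name = "c",
                                      atc_subgroup = "c", n_periods = "i",
                                      n_subjects = "i", year = "i"))
  subjects <- read_checked(subjects_path, subjects_schema,
                           readr::cols(study_id = "c", subject_id = "c",
                                       cmax_test = "d", cmax_ref = "d",
                                       cmax_unit = "c", auc_test = "d",
                                       auc_ref = "d", auc_unit = "c"))
  events <- read_checked(events_path, events_schema,
                         readr::cols(study_id = "c", subject_id = "c",
                                     ae_type = "c", period = "c",
                                     serious = "l", drug_arm = "c"))

  fill_unit <- function(u, parameter) {
    u[is.na(u) | !nzchar(u)] <- canonical_unit(parameter)
    u
  }
  cu <- fill_unit(subjects$cmax_unit, "cmax")
  au <- fill_unit(subjects$auc_unit, "auc")
  subjects$cmax_test <- harmonize_units(subjects$cmax_test, cu, "cmax", units)
  subjects$cmax_ref <- harmonize_units(subjects$cmax_ref, cu, "cmax", units)
  subjects$auc_test <- harmonize_units(subjects$auc_test, au, "auc", units)
  subjects$auc_ref <- harmonize_units(subjects$auc_ref, au, "auc", units)
  subjects$cmax_unit <- NULL
  subjects$auc_unit <- NULL

  be_dataset(studies, subjects, events)
}

#' Write a BE dataset to three CSV files
#'
#' Emits `studies.csv`, `subjects.csv` and `adverse_events.csv` in the schema
#' read by [read_dataset()], with PK values in canonical units. Reading the
#' written files reproduces the dataset field for field.
#'
#' @param dataset a validated `be_dataset`.
#' @param out_dir output directory; created if absent.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  validate_dataset(dataset)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_besplit(paste0("cannot create directory: ", out_dir), "besplit_io_error")
  }
  paths <- c(
    studies = file.path(out_dir, "studies.csv"),
    subjects = file.path(out_dir, "subjects.csv"),
    adverse_events = file.path(out_dir, "adverse_events.csv")
  )
  st <- dataset$studies[, studies_schema]
  su <- dataset$subjects
  su_out <- tibble::tibble(
    study_id = su$study_id,
    subject_id = su$subject_id,
    cmax_test = su$cmax_test,
    cmax_ref = su$cmax_ref,
    cmax_unit = ifelse(is.na(su$cmax_test), "", canonical_unit("cmax")),
    auc_test = su$auc_test,
    auc_ref = su$auc_ref,
    auc_unit = ifelse(is.na(su$auc_test), "", canonical_unit("auc"))
  )
  ev <- dataset$adverse_events[, events_schema]
  readr::write_csv(st, paths[["studies"]], progress = FALSE)
  readr::write_csv(su_out, paths[["subjects"]], progress = FALSE)
  readr::write_csv(ev, paths[["adverse_events"]], progress = FALSE)
  invisible(paths)
}
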