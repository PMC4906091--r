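#' Run the pooled BE analysis pipeline
#'
#' Single entry point tying the stages together; the thin command-line
#' wrapper in `inst/cli/besplit.R` maps shell arguments onto this function.
#' Subcommands:
#'
#' * `simulate` — generate a synthetic dataset from a preset and write its
#'   three CSVs;
#' * `validate` — load and validate a dataset;
#' * `preprocess` — log-scale normality checks and paired test/reference
#'   comparisons of the pooled PK values (`preprocess.tsv`);
#' * `split` — per-study split points (`splits_cmax.tsv` / `splits_auc.tsv`);
#' * `pool` — pooled above/below summaries: overall (`table4.tsv`) and per
#'   ATC subgroup (`table5.tsv` for Cmax, `table6.tsv` for AUC);
#' * `summarize` — descriptive tables (`table2.tsv` subgroup frequencies,
#'   `table3.tsv` AE types by period);
#' * `all` — everything above in order.
#'
#' Every run writes `manifest.json` (configuration echo, seed, package
#' version, row counts, output list) sufficient to reproduce it; on a stage
#' failure the manifest records the failing stage before the error is
#' re-signalled. Identical configuration and seed give byte-identical
#' outputs.
#'
#' @param subcommand one of `simulate`, `validate`, `preprocess`, `split`,
#'   `pool`, `summarize`, `all`.
#' @param preset `"paper_fixture"` or a [scenario_presets()] name; exactly
#'   one of `preset` and the three paths must be supplied.
#' @param studies,subjects,events CSV paths, see [read_dataset()].
#' @param parameter `"cmax"`, `"auc"` or `"both"` (default) for the split
#'   stages.
#' @param criterion split criterion, see [split_criterion()].
#' @param alpha significance level for the preprocessing tests.
#' @param seed overrides the preset's seed when simulating.
#' @param out_dir output directory, created if needed.
#' @param verbose log per-study candidate counts and chosen splits.
#' @return Invisibly, a named list of written file paths.
#' @export
run_pipeline <- function(subcommand = c("all", "simulate", "validate",
                                        "preprocess", "split", "pool",
                                        "summarize"),
                         preset = NULL, studies = NULL, subjects = NULL,
                         events = NULL, parameter = "both",
                         criterion = c("weighted", "unweighted-sum"),
                         alpha = 0.05, seed = NULL, out_dir = ".",
                         verbose = FALSE) {
  subcommand <- match.arg(subcommand)
  criterion <- match.arg(criterion)
  have_paths <- !is.null(studies) || !is.null(subjects) || !is.null(events)
  if (is.null(preset) == !have_paths) {
    stop_besplit("supply exactly one of a preset name or the three CSV paths",
                 "besplit_validation_error")
  }
  if (have_paths && (is.null(studies) || is.null(subjects) || is.null(events))) {
    stop_besplit("all three CSV paths (studies, subjects, events) are required",
                 "besplit_validation_error")
  }
  params <- if (parameter == "both") c("cmax", "auc") else match_parameter(parameter)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  outputs <- character(0)
  counts <- list()
  stage <- "load"
  manifest_path <- file.path(out_dir, "manifest.json")
  write_manifest <- function(status, failed_stage = NULL) {
    manifest <- list(
      subcommand = subcommand,
      preset = preset,
      inputs = if (have_paths) list(studies = studies, subjects = subjects,
                                    events = events),
      parameter = parameter,
      criterion = criterion,
      alpha = alpha,
      seed = seed,
      package = "besplit",
      package_version = as.character(utils::packageVersion("besplit")),
      row_counts = counts,
      outputs = as.list(basename(outputs)),
      status = status,
      failed_stage = failed_stage
    )
    jsonlite::write_json(manifest[!vapply(manifest, is.null, logical(1))],
                         manifest_path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(df, path, progress = FALSE)
    outputs <<- c(outputs, path)
    path
  }
  log_msg <- function(...) if (verbose) message(sprintf(...))

  result <- tryCatch({
    ds <- if (!is.null(preset)) {
      if (preset == "paper_fixture") {
        paper_fixture()
      } else {
        presets <- scenario_presets()
        if (!preset %in% names(presets)) {
          stop_besplit(paste0("unknown preset: ", preset, " (expected paper_fixture, ",
                              paste(names(presets), collapse = ", "), ")"),
                       "besplit_validation_error")
        }
        cfg <- presets[[preset]]
        if (!is.null(seed)) cfg$seed <- as.integer(seed)
        generate_dataset(cfg)
      }
    } else {
      read_dataset(studies, subjects, events)
    }
    counts <- list(studies = nrow(ds$studies), subjects = nrow(ds$subjects),
                   adverse_events = nrow(ds$adverse_events))

    if (subcommand == "simulate") {
      stage <- "simulate"
      outputs <- c(outputs, write_dataset(ds, out_dir))
    }
    if (subcommand == "validate") {
      stage <- "validate"
      validate_dataset(ds)
    }
    if (subcommand %in% c("preprocess", "all")) {
      stage <- "preprocess"
      pk <- ds$subjects[!is.na(ds$subjects$cmax_test), ]
      if (nrow(pk) >= 5) {
        rows <- list()
        for (p in c("cmax", "auc")) {
          for (arm in c("test", "ref")) {
            v <- pk[[paste0(p, "_", arm)]]
            nc <- normality_check(log_transform(v), alpha)
            rows[[length(rows) + 1L]] <- tibble::tibble(
              check = "ks_normality", parameter = p, arm = arm,
              statistic = nc$statistic, p_value = nc$p_value,
              verdict = ifelse(nc$normal, "normal", "non-normal")
            )
          }
          pc <- paired_comparison(pk[[paste0(p, "_test")]],
                                  pk[[paste0(p, "_ref")]], alpha, p)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            check = "paired_t", parameter = p, arm = "test-vs-ref",
            statistic = pc$statistic, p_value = pc$p_value,
            verdict = ifelse(pc$significant, "different", "equivalent-mean")
          )
        }
        emit(dplyr::bind_rows(rows), "preprocess.tsv")
      } else if (subcommand == "preprocess") {
        stop_besplit("preprocess requires at least 5 subjects with PK values",
                     "besplit_validation_error")
      }
    }
    splits <- list()
    if (subcommand %in% c("split", "pool", "all")) {
      stage <- "split"
      if (!any(ds$studies$has_pk)) {
        stop_besplit("no study has has_pk = TRUE (complete Cmax/AUC values); nothing to split",
                     "besplit_validation_error")
      }
      for (p in params) {
        sr <- study_splits(ds, p, criterion)
        splits[[p]] <- sr
        for (j in seq_len(nrow(sr))) {
          log_msg("split %s %s: %d candidates, v = %g", sr$study_id[j], p,
                  sr$candidates_evaluated[j], sr$split_value[j])
        }
        emit(sr, paste0("splits_", p, ".tsv"))
      }
    }
    if (subcommand %in% c("pool", "all")) {
      stage <- "pool"
      overall <- dplyr::bind_rows(lapply(splits, pool_splits, dataset = ds))
      emit(overall, "table4.tsv")
      if ("cmax" %in% params) {
        emit(pool_splits(splits[["cmax"]], ds, by_subgroup = TRUE), "table5.tsv")
      }
      if ("auc" %in% params) {
        emit(pool_splits(splits[["auc"]], ds, by_subgroup = TRUE), "table6.tsv")
      }
    }
    if (subcommand %in% c("summarize", "all")) {
      stage <- "summarize"
      emit(subgroup_frequency_table(ds), "table2.tsv")
      emit(ae_type_table(ds), "table3.tsv")
      of <- overall_frequencies(ds)
      counts$ae_per_study <- of$per_study
      counts$ae_per_volunteer <- of$per_volunteer
    }
    stage <- "manifest"
    write_manifest("ok")
    outputs <- c(outputs, manifest_path)
    invisible(stats::setNames(as.list(outputs), basename(unlist(outputs))))
  }, besplit_error = function(e) {
    write_manifest("failed", failed_stage = stage)
    stop(e)
  })
  result
}
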