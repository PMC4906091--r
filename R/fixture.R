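# Deterministic reference dataset reproducing the printed marginal counts of
# a pooled BE database: 261 studies / 7828 volunteers / 1642 adverse events,
# with a 63-study PK-bearing subset (1992 subjects) whose per-study Gini
# splits pool to the published below/above contingency counts, overall and
# per ATC subgroup. Only the counts are contractual; individual PK values
# are synthetic and exist to drive the split search to the intended
# boundaries.

fixture_subgroups <- function() {
  tibble::tibble(
    atc_subgroup = atc_subgroups(),
    n_studies = c(66L, 56L, 46L, 42L, 39L, 8L, 2L, 2L),
    n_volunteers = c(2095L, 1409L, 1595L, 1280L, 1121L, 228L, 48L, 52L),
    n_events = c(355L, 126L, 108L, 276L, 681L, 27L, 48L, 21L)
  )
}

# AE type x period contingency (periods I, II, III, IV, washout/predose).
# The long tail of infrequent event types is represented by ten labels so
# that the named five remain the most frequent.
fixture_type_period <- function() {
  named <- rbind(
    headache = c(262, 260, 5, 0, 0),
    somnolence = c(130, 129, 0, 0, 0),
    nausea = c(100, 93, 1, 1, 0),
    dizziness = c(61, 55, 0, 0, 0),
    vomiting = c(34, 19, 0, 0, 1)
  )
  other_labels <- c("fatigue", "dyspepsia", "abdominal pain", "dry mouth",
                    "insomnia", "palpitation", "rash", "diarrhoea",
                    "epistaxis", "back pain")
  other_totals <- c(283, 202, 0, 0, 6)
  other <- sapply(seq_along(other_totals), function(p) {
    tot <- other_totals[p]
    base <- tot %/% 10L
    extra <- tot %% 10L
    base + as.integer(seq_len(10) <= extra)
  })
  rownames(other) <- other_labels
  m <- rbind(named, other)
  colnames(m) <- ae_periods()
  m
}

# Structured PK studies per subgroup. kind encodes where the flagged
# (adverse-event) subjects sit relative to the study's own split: first
# letter = Cmax side ("d" below / "u" above), second = AUC side. w = AE
# count carried by the k flagged subjects; m = unflagged subjects on the
# opposite side. Such a study has a unique perfect split on the binary
# flag, so the boundary (hence the side counts) is forced. padding lists
# sizes of zero-AE studies, whose degenerate split falls at the median
# candidate (half below, half above). The layout sums exactly to the
# published per-subgroup below/above margins for both parameters.
fixture_pk_layout <- function() {
  list(
    "cardiovascular system" = list(
      studies = list(c(kind = "dd", w = 15, k = 8, m = 2),
                     c(kind = "du", w = 2, k = 1, m = 44),
                     c(kind = "uu", w = 17, k = 9, m = 65)),
      padding = rep(22L, 9)
    ),
    "antiinfectives for systemic use" = list(
      studies = list(c(kind = "dd", w = 10, k = 5, m = 131),
                     c(kind = "du", w = 1, k = 1, m = 3),
                     c(kind = "uu", w = 14, k = 7, m = 48)),
      padding = rep(24L, 9)
    ),
    "musculo-skeletal system" = list(
      studies = list(c(kind = "dd", w = 6, k = 3, m = 109),
                     c(kind = "du", w = 5, k = 3, m = 1),
                     c(kind = "ud", w = 1, k = 1, m = 54),
                     c(kind = "uu", w = 9, k = 5, m = 4)),
      padding = rep(24L, 6)
    ),
    "alimentary tract and metabolism" = list(
      studies = list(c(kind = "dd", w = 19, k = 10, m = 96),
                     c(kind = "du", w = 8, k = 4, m = 21),
                     c(kind = "uu", w = 66, k = 33, m = 4)),
      padding = rep(26L, 7)
    ),
    "nervous system" = list(
      studies = list(c(kind = "dd", w = 40, k = 20, m = 27),
                     c(kind = "du", w = 30, k = 15, m = 1),
                     c(kind = "ud", w = 10, k = 5, m = 22),
                     c(kind = "uu", w = 57, k = 29, m = 66)),
      padding = rep(28L, 9)
    ),
    "respiratory system" = list(
      studies = list(c(kind = "dd", w = 1, k = 1, m = 43),
                     c(kind = "du", w = 1, k = 1, m = 25),
                     c(kind = "ud", w = 9, k = 5, m = 1)),
      padding = rep(10L, 2)
    )
  )
}

# k ones among n slots, as evenly interleaved as possible.
spread_ones <- function(n, k) {
  v <- rep(0L, n)
  if (k > 0) v[ceiling(seq_len(k) * n / k)] <- 1L
  v
}

# The genito-urinary subgroup has two studies in total, so its whole PK
# contingency must come from one 47-subject study. The flag arrangements
# below make the weighted-Gini argmin fall exactly after 12 subjects (Cmax)
# and 15 subjects (AUC), the published below-side sizes; each flagged
# subject carries one adverse event.
fixture_genito_study <- function() {
  flags_by_cmax <- c(rep(1L, 3), rep(0L, 9), rev(spread_ones(35, 27)))
  flags_by_auc <- c(rep(1L, 5), rep(0L, 10), rev(spread_ones(32, 25)))
  n <- length(flags_by_cmax)
  auc_rank <- integer(n)
  auc_rank[flags_by_cmax == 1] <- which(flags_by_auc == 1)
  auc_rank[flags_by_cmax == 0] <- which(flags_by_auc == 0)
  tibble::tibble(
    cmax_rank = seq_len(n),
    auc_rank = auc_rank,
    ae_count = flags_by_cmax
  )
}

# Subject layout for one structured study: cmax_rank order, with the k
# flagged subjects as a block at the bottom/top per `kind`, and an AUC rank
# permutation placing the same block per the second letter. AE counts of 2
# and 1 spread w events over the k flagged subjects.
structured_subjects <- function(kind, w, k, m) {
  n <- k + m
  flags_c <- if (substr(kind, 1, 1) == "d") {
    c(rep(1L, k), rep(0L, m))
  } else {
    c(rep(0L, m), rep(1L, k))
  }
  flags_a <- if (substr(kind, 2, 2) == "d") {
    c(rep(1L, k), rep(0L, m))
  } else {
    c(rep(0L, m), rep(1L, k))
  }
  auc_rank <- integer(n)
  auc_rank[flags_c == 1] <- which(flags_a == 1)
  auc_rank[flags_c == 0] <- which(flags_a == 0)
  counts <- c(rep(2L, w - k), rep(1L, 2 * k - w))
  ae <- integer(n)
  ae[flags_c == 1] <- counts
  tibble::tibble(cmax_rank = seq_len(n), auc_rank = auc_rank, ae_count = ae)
}

#' Deterministic fixture dataset with the published marginal counts
#'
#' Builds a fully synthetic 261-study BE dataset whose marginal counts equal
#' the published tables of the pooled database it emulates: study, volunteer
#' and adverse-event totals per ATC subgroup; adverse-event types and
#' crossover periods; and a 63-study PK subset (1992 subjects) whose
#' per-study Gini split points pool to the published below/above
#' adverse-event and subject counts for both Cmax and AUC, overall and per
#' subgroup. Individual PK values, identifiers and event labels are
#' synthetic; only the counts are contractual.
#'
#' @return A validated [be_dataset()].
#' @export
#' @examples
#' fx <- paper_fixture()
#' nrow(fx$adverse_events)  # 1642
paper_fixture <- function() {
  sg <- fixture_subgroups()
  layout <- fixture_pk_layout()

  studies <- list()
  subjects <- list()
  pk_slots <- list()     # AE slots in PK studies: study_id, subject_id, count
  nonpk_meta <- list()

  study_idx <- 0L
  next_study <- function() {
    study_idx <<- study_idx + 1L
    sprintf("S%03d", study_idx)
  }

  for (g in seq_len(nrow(sg))) {
    label <- sg$atc_subgroup[g]
    pk_n <- 0L
    pk_ae <- 0L

    add_pk_study <- function(subj_layout, year) {
      sid <- next_study()
      n <- nrow(subj_layout)
      studies[[length(studies) + 1L]] <<- tibble::tibble(
        study_id = sid,
        api_name = sprintf("API-%03d", ((study_idx - 1L) %% 109L) + 1L),
        atc_subgroup = label,
        n_periods = 2L,
        n_subjects = n,
        year = year
      )
      subjects[[length(subjects) + 1L]] <<- tibble::tibble(
        study_id = sid,
        subject_id = sprintf("V%02d", seq_len(n)),
        cmax_test = (50 + subj_layout$cmax_rank) * 1.02,
        cmax_ref = (50 + subj_layout$cmax_rank) * 0.98,
        auc_test = (400 + 3 * subj_layout$auc_rank) * 1.02,
        auc_ref = (400 + 3 * subj_layout$auc_rank) * 0.98,
        ae_count_planned = subj_layout$ae_count
      )
      flagged <- which(subj_layout$ae_count > 0)
      if (length(flagged) > 0) {
        pk_slots[[length(pk_slots) + 1L]] <<- tibble::tibble(
          study_id = sid,
          subject_id = sprintf("V%02d", flagged),
          count = subj_layout$ae_count[flagged]
        )
      }
      invisible(sid)
    }

    if (label == "genito-urinary system and sex hormones") {
      add_pk_study(fixture_genito_study(), 2008L)
      pk_n <- 47L
      pk_ae <- 30L
    } else if (!is.null(layout[[label]])) {
      lay <- layout[[label]]
      for (stdef in lay$studies) {
        sl <- structured_subjects(stdef[["kind"]], as.integer(stdef[["w"]]),
                                  as.integer(stdef[["k"]]), as.integer(stdef[["m"]]))
        add_pk_study(sl, 2006L + (study_idx %% 8L))
        pk_n <- pk_n + nrow(sl)
        pk_ae <- pk_ae + sum(sl$ae_count)
      }
      for (psize in lay$padding) {
        sl <- tibble::tibble(cmax_rank = seq_len(psize),
                             auc_rank = seq_len(psize),
                             ae_count = rep(0L, psize))
        add_pk_study(sl, 2006L + (study_idx %% 8L))
        pk_n <- pk_n + psize
      }
    }

    # non-PK remainder of the subgroup
    np_studies <- sg$n_studies[g] - sum(vapply(studies, function(s)
      s$atc_subgroup == label, logical(1)))
    np_subjects <- sg$n_volunteers[g] - pk_n
    np_events <- sg$n_events[g] - pk_ae
    if (np_studies > 0) {
      base <- np_subjects %/% np_studies
      sizes <- rep(base, np_studies) + as.integer(seq_len(np_studies) <= np_subjects %% np_studies)
      subj_seen <- 0L
      for (s in seq_len(np_studies)) {
        sid <- next_study()
        n <- sizes[s]
        # the four-/three-period designs live among the cardiovascular
        # non-PK studies so that period III/IV events have a legal home
        n_periods <- 2L
        if (label == "cardiovascular system") {
          if (s <= 20) n_periods <- 4L else if (s == 21) n_periods <- 3L
        }
        studies[[length(studies) + 1L]] <- tibble::tibble(
          study_id = sid,
          api_name = sprintf("API-%03d", ((study_idx - 1L) %% 109L) + 1L),
          atc_subgroup = label,
          n_periods = n_periods,
          n_subjects = n,
          year = 2000L + (study_idx %% 6L)
        )
        # events cycle over the subgroup's non-PK subjects in order
        subj_global <- subj_seen + seq_len(n)
        ae_counts <- vapply(subj_global, function(j) {
          if (np_subjects == 0) 0L else
            sum(((seq_len(np_events) - 1L) %% np_subjects) + 1L == j)
        }, integer(1))
        subjects[[length(subjects) + 1L]] <- tibble::tibble(
          study_id = sid,
          subject_id = sprintf("V%02d", seq_len(n)),
          cmax_test = NA_real_, cmax_ref = NA_real_,
          auc_test = NA_real_, auc_ref = NA_real_,
          ae_count_planned = ae_counts
        )
        flagged <- which(ae_counts > 0)
        if (length(flagged) > 0) {
          nonpk_meta[[length(nonpk_meta) + 1L]] <- tibble::tibble(
            study_id = sid,
            subject_id = sprintf("V%02d", flagged),
            count = ae_counts[flagged]
          )
        }
        subj_seen <- subj_seen + n
      }
    }
  }

  studies <- dplyr::bind_rows(studies)
  subjects <- dplyr::bind_rows(subjects)

  # Expand AE slots: non-PK first (ordered as constructed, cardiovascular
  # leading, so period III/IV labels land in multi-period studies), then PK.
  expand <- function(meta) {
    if (length(meta) == 0) return(tibble::tibble(study_id = character(0),
                                                 subject_id = character(0)))
    m <- dplyr::bind_rows(meta)
    tibble::tibble(
      study_id = rep(m$study_id, m$count),
      subject_id = rep(m$subject_id, m$count)
    )
  }
  slots <- dplyr::bind_rows(expand(nonpk_meta), expand(pk_slots))

  # (type, period) labels: the seven period III/IV events first, then the
  # remainder in type-major order.
  tp <- fixture_type_period()
  labs <- expand.grid(ae_type = rownames(tp), period = colnames(tp),
                      stringsAsFactors = FALSE)
  labs$count <- as.vector(tp)
  labs <- labs[labs$count > 0, ]
  late <- labs$period %in% c("III", "IV")
  labs <- rbind(labs[late, ], labs[!late, ])
  labels <- tibble::tibble(
    ae_type = rep(labs$ae_type, labs$count),
    period = rep(labs$period, labs$count)
  )
  stopifnot(nrow(labels) == nrow(slots))

  pk_study_ids <- studies$study_id[!is.na(subjects$cmax_test[match(studies$study_id, subjects$study_id)])]
  events <- tibble::tibble(
    study_id = slots$study_id,
    subject_id = slots$subject_id,
    ae_type = labels$ae_type,
    period = labels$period,
    serious = FALSE,
    drug_arm = "unknown"
  )
  in_pk <- events$study_id %in% pk_study_ids
  events$drug_arm[in_pk] <- rep_len(c("test", "reference"), sum(in_pk))
  # four serious events among the long-tail types, one in washout
  other_types <- setdiff(rownames(tp),
                         c("headache", "somnolence", "nausea", "dizziness", "vomiting"))
  wo <- which(events$period == "washout_or_predose" & events$ae_type %in% other_types)
  pi <- which(events$period == "I" & events$ae_type %in% other_types)
  events$serious[c(wo[1], pi[1:3])] <- TRUE

  subjects$ae_count_planned <- NULL
  be_dataset(studies, subjects, events)
}
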