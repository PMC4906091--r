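#' Configuration for the synthetic BE-data generator
#'
#' Parameterizes a simulated pooled-BE database with the statistical
#' structure the split-point analysis assumes: per-study lognormal Cmax and
#' AUC with within-subject test/reference variability, a latent PK threshold
#' at which the per-subject adverse-event probability steps from `p_below`
#' to `p_above`, and categorical AE type / period / ATC subgroup
#' distributions.
#'
#' @param n_studies number of studies to simulate.
#' @param subjects_per_study scalar or per-study vector of cohort sizes.
#' @param pk_mu,pk_sigma location and scale of log-Cmax (log ng/mL) per
#'   study; recycled over studies.
#' @param auc_mu,auc_sigma same for log-AUC (log ng.h/mL).
#' @param pk_auc_cor correlation of the subject-level log-Cmax and log-AUC
#'   latent terms (default 0.8), so both parameters show similar split
#'   behaviour.
#' @param within_subject_sd standard deviation of the independent test and
#'   reference deviations on the log scale.
#' @param threshold_theta latent split value on mean Cmax (ng/mL); recycled
#'   over studies.
#' @param p_below,p_above per-subject adverse-event probabilities (or
#'   Poisson rates under `count_model = "poisson"`) for mean Cmax at or
#'   below / above the threshold; must satisfy
#'   `0 <= p_below <= p_above <= 1`.
#' @param ae_type_weights named nonnegative weights over AE-type labels.
#' @param period_weights named nonnegative weights over the period labels of
#'   [ae_periods()]; periods beyond a study's design are excluded at draw
#'   time.
#' @param subgroup_weights named nonnegative weights over [atc_subgroups()].
#' @param count_model `"bernoulli"` (at most one AE per subject, the
#'   default) or `"poisson"` (AE counts with the same side-dependent rate).
#' @param serious_rate probability that an event is serious.
#' @param pk_studies how many studies carry recorded Cmax/AUC values
#'   (default all); the remainder mimic studies whose PK was never digitized
#'   (the latent values still drive AE occurrence, they are just not
#'   recorded).
#' @param seed root seed; each study derives an independent child stream, so
#'   enlarging `n_studies` does not perturb earlier studies.
#' @return An object of class `be_synth_config`.
#' @export
synthetic_config <- function(n_studies,
                             subjects_per_study,
                             pk_mu = log(100),
                             pk_sigma = 0.4,
                             auc_mu = log(1000),
                             auc_sigma = 0.4,
                             pk_auc_cor = 0.8,
                             within_subject_sd = 0.15,
                             threshold_theta = 100,
                             p_below = 0.1,
                             p_above = 0.2,
                             ae_type_weights = default_ae_type_weights(),
                             period_weights = default_period_weights(),
                             subgroup_weights = default_subgroup_weights(),
                             count_model = c("bernoulli", "poisson"),
                             serious_rate = 4 / 1642,
                             pk_studies = n_studies,
                             seed = 1L) {
  count_model <- match.arg(count_model)
  if (n_studies < 1) {
    stop_besplit("n_studies must be >= 1", "besplit_validation_error")
  }
  if (any(subjects_per_study < 1)) {
    stop_besplit("subjects_per_study must be >= 1", "besplit_validation_error")
  }
  if (!(p_below >= 0 && p_below <= p_above && p_above <= 1)) {
    stop_besplit("need 0 <= p_below <= p_above <= 1 (the threshold model is monotone by construction)",
                 "besplit_validation_error")
  }
  if (any(c(pk_sigma, auc_sigma) <= 0) || within_subject_sd < 0) {
    stop_besplit("scale parameters must be positive", "besplit_validation_error")
  }
  if (abs(pk_auc_cor) > 1) {
    stop_besplit("pk_auc_cor must lie in [-1, 1]", "besplit_validation_error")
  }
  for (w in list(ae_type_weights, period_weights, subgroup_weights)) {
    if (any(w < 0) || sum(w) <= 0 || is.null(names(w))) {
      stop_besplit("categorical weights must be named, nonnegative, not all zero",
                   "besplit_validation_error")
    }
  }
  if (!all(names(period_weights) %in% ae_periods()) ||
      !all(names(subgroup_weights) %in% atc_subgroups())) {
    stop_besplit("period/subgroup weight names must come from the closed label sets",
                 "besplit_validation_error")
  }
  if (pk_studies < 0 || pk_studies > n_studies) {
    stop_besplit("pk_studies must lie in [0, n_studies]", "besplit_validation_error")
  }
  structure(list(
    n_studies = as.integer(n_studies),
    subjects_per_study = as.integer(subjects_per_study),
    pk_mu = pk_mu, pk_sigma = pk_sigma,
    auc_mu = auc_mu, auc_sigma = auc_sigma,
    pk_auc_cor = pk_auc_cor,
    within_subject_sd = within_subject_sd,
    threshold_theta = threshold_theta,
    p_below = p_below, p_above = p_above,
    ae_type_weights = ae_type_weights,
    period_weights = period_weights,
    subgroup_weights = subgroup_weights,
    count_model = count_model,
    serious_rate = serious_rate,
    pk_studies = as.integer(pk_studies),
    seed = as.integer(seed)
  ), class = "be_synth_config")
}

#' @rdname synthetic_config
#' @export
default_ae_type_weights <- function() {
  c(headache = 527, somnolence = 259, nausea = 195, dizziness = 116,
    vomiting = 54, "other adverse events" = 491)
}

#' @rdname synthetic_config
#' @export
default_period_weights <- function() {
  stats::setNames(c(870, 758, 6, 1, 7), ae_periods())
}

#' @rdname synthetic_config
#' @export
default_subgroup_weights <- function() {
  stats::setNames(c(66, 56, 46, 42, 39, 8, 2, 2), atc_subgroups())
}

child_seed <- function(seed, i) {
  as.integer((as.double(seed) + 1000003 * i) %% 2147483629)
}

#' Generate a synthetic BE dataset
#'
#' Per study: each subject receives a latent log-Cmax drawn from the study's
#' normal law and a correlated log-AUC; test and reference values are the
#' exponentiated latent mean plus independent within-subject deviations.
#' Adverse events occur with probability `p_below` or `p_above` according to
#' whether the subject's arithmetic-mean Cmax is at or below / above
#' `threshold_theta`; each event receives a type and period from the
#' configured weights. Identical `(seed, config)` give an identical dataset.
#'
#' @param config a [synthetic_config()].
#' @return A validated [be_dataset()].
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "be_synth_config")) {
    stop_besplit("config must be a be_synth_config", "besplit_validation_error")
  }
  n_per <- rep_len(config$subjects_per_study, config$n_studies)
  theta <- rep_len(config$threshold_theta, config$n_studies)
  pk_mu <- rep_len(config$pk_mu, config$n_studies)
  pk_sigma <- rep_len(config$pk_sigma, config$n_studies)
  auc_mu <- rep_len(config$auc_mu, config$n_studies)
  auc_sigma <- rep_len(config$auc_sigma, config$n_studies)
  rho <- config$pk_auc_cor

  studies <- vector("list", config$n_studies)
  subjects <- vector("list", config$n_studies)
  events <- vector("list", config$n_studies)

  for (i in seq_len(config$n_studies)) {
    set.seed(child_seed(config$seed, i))
    sid <- sprintf("S%04d", i)
    n <- n_per[i]
    has_pk <- i <= config$pk_studies

    subgroup <- sample(names(config$subgroup_weights), 1,
                       prob = config$subgroup_weights)
    n_periods <- sample(c(2L, 3L, 4L), 1, prob = c(240, 1, 20))

    zc <- stats::rnorm(n)
    za <- stats::rnorm(n)
    log_cmax <- pk_mu[i] + pk_sigma[i] * zc
    log_auc <- auc_mu[i] + auc_sigma[i] * (rho * zc + sqrt(1 - rho^2) * za)
    dev <- function() stats::rnorm(n, 0, config$within_subject_sd)
    cmax_test <- exp(log_cmax + dev())
    cmax_ref <- exp(log_cmax + dev())
    auc_test <- exp(log_auc + dev())
    auc_ref <- exp(log_auc + dev())

    cmax_mean <- (cmax_test + cmax_ref) / 2
    p <- ifelse(cmax_mean <= theta[i], config$p_below, config$p_above)
    ae_count <- if (config$count_model == "bernoulli") {
      stats::rbinom(n, 1L, p)
    } else {
      stats::rpois(n, p)
    }

    studies[[i]] <- tibble::tibble(
      study_id = sid,
      api_name = sprintf("API-%03d", ((i - 1L) %% 109L) + 1L),
      atc_subgroup = subgroup,
      n_periods = n_periods,
      n_subjects = n,
      year = 2000L + (i %% 14L)
    )
    subjects[[i]] <- tibble::tibble(
      study_id = sid,
      subject_id = sprintf("V%04d", seq_len(n)),
      cmax_test = if (has_pk) cmax_test else NA_real_,
      cmax_ref = if (has_pk) cmax_ref else NA_real_,
      auc_test = if (has_pk) auc_test else NA_real_,
      auc_ref = if (has_pk) auc_ref else NA_real_
    )
    n_ev <- sum(ae_count)
    if (n_ev > 0) {
      period_w <- config$period_weights
      allowed <- c(ae_periods()[seq_len(n_periods)], "washout_or_predose")
      period_w <- period_w[names(period_w) %in% allowed]
      events[[i]] <- tibble::tibble(
        study_id = sid,
        subject_id = rep(sprintf("V%04d", seq_len(n)), ae_count),
        ae_type = sample(names(config$ae_type_weights), n_ev, replace = TRUE,
                         prob = config$ae_type_weights),
        period = sample(names(period_w), n_ev, replace = TRUE,
                        prob = period_w),
        serious = stats::runif(n_ev) < config$serious_rate,
        drug_arm = sample(c("test", "reference"), n_ev, replace = TRUE)
      )
    }
  }

  events <- events[!vapply(events, is.null, logical(1))]
  ev <- if (length(events) == 0) {
    tibble::tibble(study_id = character(0), subject_id = character(0),
                   ae_type = character(0), period = character(0),
                   serious = logical(0), drug_arm = character(0))
  } else {
    dplyr::bind_rows(events)
  }
  be_dataset(dplyr::bind_rows(studies), dplyr::bind_rows(subjects), ev)
}

#' Named scenario presets for the generator
#'
#' * `"null"`: 200 studies of 50 subjects with `p_below == p_above` — no
#'   true split, used for direction-calibration checks.
#' * `"step"`: one study of 5000 subjects with a strong step
#'   (`theta = 100`, `p_below = 0.1`, `p_above = 0.4`) — used for
#'   threshold-recovery experiments.
#' * `"paper_like"`: 261 studies of which 63 carry PK, with ATC subgroup and
#'   AE-type weights matching the published study-count and event-type
#'   distributions, and a modest step at the pooled published
#'   probabilities.
#'
#' @return Named list of [synthetic_config()] objects.
#' @export
scenario_presets <- function() {
  list(
    null = synthetic_config(
      n_studies = 200, subjects_per_study = 50,
      threshold_theta = 100, p_below = 0.2, p_above = 0.2, seed = 20L
    ),
    step = synthetic_config(
      n_studies = 1, subjects_per_study = 5000,
      threshold_theta = 100, p_below = 0.1, p_above = 0.4, seed = 7L
    ),
    paper_like = synthetic_config(
      n_studies = 261, subjects_per_study = 30, pk_studies = 63,
      threshold_theta = 100, p_below = 0.165, p_above = 0.185, seed = 42L
    )
  )
}
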