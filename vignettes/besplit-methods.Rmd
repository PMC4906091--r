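---
title: "Split-point estimation for adverse events in pooled bioequivalence studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Split-point estimation for adverse events in pooled bioequivalence studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(besplit)
```

## The problem

Bioequivalence (BE) trials compare a generic (test) formulation against the
originator (reference) in healthy volunteers, almost always in a crossover
design: every subject receives both drugs in separate periods with a washout
between them. The two pharmacokinetic endpoints are the maximum observed
concentration `Cmax` (ng/mL) and the area under the concentration–time curve
`AUC` (ng·h/mL). Contract research organisations accumulate hundreds of such
studies, together with the adverse events (AEs) recorded per subject and
period. Pooling them opens a question a single trial cannot answer: *do
subjects with higher drug exposure experience adverse events more often?*

`besplit` addresses that question with a deliberately simple device: for
each study, a one-split decision stump on the subject's arithmetic mean of
test and reference PK values against the binary class "subject had at least
one adverse event". The per-study splits are then pooled — events and
subjects below versus above each study's own split point are summed across
studies, overall and per ATC (Anatomical Therapeutic Chemical) level-1 drug
subgroup — giving below/above AE probabilities whose comparison is the
study-level finding of interest.

## The split criterion

For a node `t` with class proportions `p(j|t)` the Gini impurity is

    GINI(t) = 1 - sum_j p(j|t)^2,

which for a binary class lies in [0, 0.5]. Candidate thresholds are the
midpoints between adjacent *distinct* sorted values of the covariate; each
candidate `v` partitions subjects into `x <= v` (below) and `x > v` (above).
`best_split()` minimizes the **weighted** average of the two child
impurities,

    G(v) = (n_L/n) GINI(L) + (n_R/n) GINI(R),

over all candidates. A single node's impurity formula does not by itself
define a split rule; the weighted-children form is the standard CART
criterion and is the reading adopted here. Minimizing an *unweighted* sum
of the two child impurities is offered as a sensitivity variant
(`criterion = "unweighted-sum"`) but is not the default, because without
the size weights the criterion does not reduce to a proper impurity
decrease and degenerates towards unbalanced splits.

Numerical choices, all deterministic:

* **Tie-break.** Ties — including values that agree only up to floating
  point, which occur for symmetric flag configurations — are resolved
  towards the smallest threshold. Criterion values within `1e-12` are
  treated as tied; with at most a few thousand subjects per study the
  smallest genuine criterion gap is orders of magnitude larger.
* **Side convention.** Below means `value <= v`. Since candidates sit
  strictly between distinct data values, equality never occurs on the data
  that produced the split; the convention matters only when a split is
  applied to new subjects.
* **Degenerate studies.** When every subject has the same class (no AE at
  all, or all AEs) or fewer than two distinct values exist, no informative
  split exists. Rather than fabricating one, the result carries
  `degenerate = TRUE` and places the split at the median candidate (or the
  single value), so pooling still assigns every subject to a side.
* **Two probabilities, one impurity.** The impurity is computed on the
  binary flag (any AE vs none), following the class definition of the
  stump. The reported `prob_below`/`prob_above` divide AE *counts* by
  subject counts, because the pooled summaries are defined that way; a
  subject with several events can therefore push a side's probability
  above 1. The package documents rather than clamps this.

`study_splits()` applies the search per study (only studies whose subjects
all carry complete Cmax and AUC values participate; the rest are listed as
skipped), and `pool_splits()` sums the per-study below/above counts into
the overall or per-subgroup contingency summaries, rounding probabilities
half-away-from-zero to 3 decimals and marking the side with the higher
probability.

Because the criterion depends on the covariate only through its ordering,
any strictly increasing transformation of the PK values leaves the chosen
split *index* unchanged — in particular the analysis is invariant to the
unit chosen, provided units were harmonized at all.

## Preprocessing

* **Units.** PK inputs are converted into canonical units (ng/mL for Cmax,
  ng·h/mL for AUC) via a multiplicative unit table
  (`default_units()`, extensible). Unknown labels are an error naming the
  label, never a silent pass-through.
* **Log transform.** PK distributions are right-skewed with variance
  increasing in the mean; all distributional checks and test/reference
  comparisons run on natural logs. The base is a cosmetic choice (the
  tests are base-invariant) but is fixed for reproducibility.
* **Normality.** `normality_check()` is a composite-normality KS test with
  the Lilliefors correction (moments estimated from the sample, via
  `nortest::lillie.test`). A fully specified reference normal would need
  stated moments, which an observational screen of measured PK variables
  does not have; the estimated-parameter variant is the defensible
  reading. Constant samples are an error (the estimated scale is zero).
* **Paired comparison.** `paired_comparison()` is a paired t-test on the
  log scale, the natural comparison for the two arms of a crossover.
  Zero-variance differences are resolved analytically (statistic 0 and
  p = 1 for identical arms, ±Inf and p = 0 for a constant non-unit ratio)
  using the same degeneracy threshold `t.test()` applies.
* **Extreme values.** `flag_extremes()` flags observations beyond 3×IQR
  from the quartiles on the log scale and removes nothing: the pipeline's
  contract is that cleaning decisions are visible, not automatic. The
  3×IQR rule is this package's choice of a conventional "extreme" fence.

## The reference fixture

`paper_fixture()` builds a deterministic 261-study dataset whose marginal
counts equal the published tables of the pooled BE database this package
was designed around: study/volunteer/event totals per ATC subgroup, AE
types by period, and a 63-study PK subset (1992 subjects) whose per-study
splits pool to the published below/above contingency counts for both Cmax
and AUC. The point of the fixture is that every published *ratio* is then
recomputed by the actual pipeline — frequencies, type shares, pooled
probabilities — rather than asserted as constants.

Only the counts are contractual. Individual PK values are synthetic and
constructed so that the split search provably lands on the intended
boundaries:

* In most structured studies the flagged (AE) subjects form a single block
  at one extreme of each PK ordering. The sorted flag sequence then has a
  unique perfect split, which any impurity criterion must select, forcing
  the below/above sizes. AE multiplicities (1–2 events per flagged
  subject) carry the event totals.
* Zero-AE "padding" studies (all even-sized) have degenerate splits at the
  median candidate, contributing exactly half their subjects to each side.
* The genito-urinary subgroup has only two studies in the published
  totals, so its entire PK contingency must come from a single 47-subject
  study; its flag arrangement interleaves flagged and unflagged subjects
  so that the weighted-Gini argmin falls exactly after the published
  below-side sizes (12 subjects for Cmax, 15 for AUC). This arrangement
  was verified numerically and is frozen in code.
* The published margins force one awkward corner: the second
  genito-urinary study must hold a single volunteer carrying 18 events.
  It is an artefact of matching printed totals, not a modelling claim.

Two published numbers are internally inconsistent with their own printed
counts and are reported as recomputed: the nervous-system frequency
(681/1121 = 60.7%, printed as 60.8) and the antiinfectives Cmax above-split
probability (14/249 = 0.056, printed as 0.055). All other printed values —
including 0.185 = 210/1138 and the antiinfectives AUC tie 0.061/0.061 —
reproduce exactly under half-away-from-zero rounding (1 decimal for
percentages, 2 for per-study/per-volunteer frequencies, 3 for
probabilities). The published per-arm event counts (352 test / 352
reference) likewise conflict with the PK-subset total of 351 implied by
the contingency tables; the tables are taken as authoritative, and the
fixture's `drug_arm` labels are explicitly non-contractual.

The published database also reports that 5498 of 7828 volunteers survived
a demographic preprocessing step whose rules are not stated; the fixture
does not model this reduction, and `describe()` exists for the summary
shape rather than for reproducing those demographic values.

## The synthetic generator

`generate_dataset()` draws data under the model the analysis assumes, so
that the estimator can be tested against a known truth:

* **Lognormal PK.** Per study, a subject's latent log-Cmax is normal
  (`pk_mu`, `pk_sigma`); test and reference values are the exponentiated
  latent mean plus independent within-subject normal deviations
  (`within_subject_sd`, default 0.15 — a typical within-subject CV for BE
  endpoints). Lognormality is the minimal law consistent with the skewed,
  variance-proportional-to-mean behaviour that motivates the log
  transform.
* **Correlated AUC.** log-AUC shares the subject-level latent term with
  log-Cmax at correlation `pk_auc_cor` (default 0.8): total exposure and
  peak concentration are strongly but not perfectly related, and both
  parameters should show similar split behaviour.
* **Step model for AEs.** A subject's AE probability is `p_below` if mean
  Cmax is at or below `threshold_theta`, else `p_above`, with
  `p_below <= p_above` enforced (the generator's model is monotone by
  construction). The default is Bernoulli (at most one AE per subject);
  `count_model = "poisson"` produces event counts with the same
  side-dependent rate, matching the count-based probability definition of
  the pooled summaries.
* **Seeding.** One root seed; every study derives a child stream, so
  enlarging a design never perturbs earlier studies, and equal
  (seed, config) gives byte-identical CSVs.

Three presets define the package's study conditions. `"step"`
(θ = 100 ng/mL, p 0.1 → 0.4, one study of 5000 subjects) has an effect
large enough that recovery failures indicate an estimator defect rather
than sampling noise; the published pooled gap (0.165 vs 0.185) is far too
small for per-study recovery at realistic cohort sizes, so preset
magnitudes are chosen for test power, not fidelity. `"null"`
(p_below = p_above = 0.2, 200 studies of 50) is the calibration scenario:
the split search always finds *some* split, and the check is that its
direction is symmetric. `"paper_like"` mirrors the published composition
(261 studies, 63 with PK, subgroup and AE-type weights from the published
distributions, 30 subjects per study) for end-to-end exercises.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: period effects and carryover, dependence of
AE risk on the drug rather than on exposure alone, MedDRA-coded event
structure, demographic covariates, and informative missingness of PK
availability (here the PK-bearing subset is simply the first
`pk_studies` studies).

## Validation problem sizes

The shipped checks run the oracle comparison on 500 random instances of up
to 30 subjects (exhaustive brute force is exact there), 100 step-scenario
replicates of 5000 subjects for threshold recovery within ±5%, one
null-scenario dataset of 200 studies for direction calibration (binomial
test at 1%), and 1000 replicates of 50 pairs for the paired-t type-I rate
(accepted band 0.03–0.07 at α = 0.05). These sizes give each check enough
resolution to fail loudly while keeping the whole suite in well under a
minute of compute.

## Known limitations

* The stump is a marginal device: it conditions on nothing (no dose, no
  body weight, no drug identity within a study) and its split value is not
  a calibrated clinical threshold.
* Pooling sums heterogeneous studies; a subgroup probability is dominated
  by its largest studies, and no meta-analytic weighting or uncertainty
  is attached to the pooled probabilities.
* Probabilities defined as counts/subjects are not proportions when
  subjects have multiple events, and the package intentionally preserves
  that definition rather than switching to subject-level proportions.
* The degenerate-study convention (median-candidate split) is arbitrary;
  it exists so pooling remains total, and such studies are flagged.
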