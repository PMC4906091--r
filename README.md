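# besplit

Gini-index split points for adverse events in pooled bioequivalence (BE)
studies.

Contract research organisations accumulate large databases of BE trials:
crossover studies in which healthy volunteers receive both a generic (test)
and an originator (reference) formulation, with the pharmacokinetic
endpoints Cmax (maximum concentration, ng/mL) and AUC (exposure, ng·h/mL)
and the adverse events (AEs) recorded per subject. Pooled across studies,
such a database can ask whether subjects with higher exposure experience
adverse events more often. `besplit` implements that analysis:

1. **Per-study split points.** For each study, subjects are described by
   the arithmetic mean of their test and reference PK values and the
   binary class "had at least one AE". The package finds the threshold *v*
   minimizing the weighted Gini impurity of the induced partition
   `{x ≤ v}` / `{x > v}`, where a node's impurity is

   GINI(t) = 1 − Σⱼ p(j|t)²

   with candidates at the midpoints between adjacent distinct sorted
   values — a one-split decision stump per study and PK parameter.
2. **Pooling.** Below/above AE and subject counts are summed across
   studies (overall and per ATC level-1 drug subgroup), giving the
   below/above AE probabilities (events ÷ subjects) that answer the
   exposure question.
3. **Descriptives and preprocessing.** AE frequency tables by subgroup,
   type and crossover period; unit harmonization; log-scale
   Lilliefors/KS normality checks and paired test-vs-reference t-tests.
4. **Synthetic data.** A seeded generator of BE datasets with lognormal
   PK, correlated Cmax/AUC and a latent AE threshold, plus a
   deterministic fixture (`paper_fixture()`) reproducing the marginal
   counts of the pooled database the method was developed on, so the
   whole pipeline can be validated end to end.

## Worked example

```r
library(besplit)

fx <- paper_fixture()
fx
#> <be_dataset> 261 studies (63 with PK), 7828 subjects, 1642 adverse events

overall_frequencies(fx)
#> $per_study
#> [1] 6.29
#> $per_volunteer
#> [1] 0.21
```

1642 adverse events over 261 studies and 7828 volunteers: 6.29 events per
study, 0.21 per volunteer. Splitting every PK-bearing study on mean Cmax
and pooling:

```r
sc <- study_splits(fx, "cmax")
pool_splits(sc, fx)
#>   stratum parameter ae_below ae_above n_below n_above prob_below prob_above higher_side
#> 1 overall cmax           141      210     854    1138      0.165      0.185 above
```

Below the per-study split points: 141 adverse events among 854 subjects
(probability 0.165); above: 210 among 1138 (0.185) — event probability is
higher on the high-exposure side. `pool_splits(sc, fx, by_subgroup = TRUE)`
gives the same contingency per ATC subgroup.

On synthetic data with a known threshold the estimator recovers it:

```r
su <- generate_dataset(scenario_presets()$step)$subjects  # theta = 100
best_split(su$cmax_mean, su$ae_flag, su$ae_count)
#> split_value 100.2221, gini_at_split 0.3305, prob_below 0.0978,
#> prob_above 0.4040, 4999 candidates evaluated
```

The true step (AE probability 0.1 below 100 ng/mL, 0.4 above) is located
within 0.3% from 5000 subjects.

A thin CLI wraps the same stages:

```sh
Rscript inst/cli/besplit.R all --preset paper_fixture --out out/
# writes table2..table6.tsv, splits_{cmax,auc}.tsv, preprocess.tsv, manifest.json
```

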