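# chemothresh

Estimates the recurrence-score threshold at which the predicted benefit of
adjuvant chemotherapy begins to outweigh its predicted harm, for
registry-style early-stage breast-cancer cohorts scored with a 21-gene
assay (Oncotype DX-type recurrence score, RS 0–100) — overall and per race.

Clinical guidelines recommend chemotherapy above fixed cutoffs (RS > 25 or
RS > 30). `chemothresh` asks the data instead: a random survival forest is
fitted to breast-cancer-specific survival on (RS, race, age, chemotherapy);
per-patient counterfactual mortality scores are computed by forcing the
treatment variable to each arm,

    risk.yes  =  predicted mortality with chemotherapy forced on
    risk.no   =  predicted mortality with chemotherapy forced off
    rel.risk  =  risk.yes − risk.no ,

`rel.risk` is smoothed against RS by local regression (tricube, span 0.75),
and the **benefit threshold** is the score where the smoothed curve crosses
zero from harm into persistent benefit. Uncertainty comes from a subsample
bootstrap (10 × 70% without replacement, median and IQR); the clinical
implication is summarised as the fold change in the number of patients above
the estimated threshold versus above the guideline cutoffs.

Registry data of this kind (the SEER Oncotype DX linkage) is
access-restricted, so the package ships a fully seeded synthetic-cohort
generator whose proportional-hazards model has a *known* race-specific
benefit threshold θ — chemotherapy's log-hazard ratio is γ(RS) = −s·(RS −
θ_race) — including RS-confounded treatment assignment (sicker patients are
treated more often) and registry-style censoring. Every stage of the
pipeline is validated by recovering θ from generated cohorts.

Audience: biostatisticians and cancer-epidemiology analysts who want a
tested, reproducible implementation of counterfactual-forest threshold
estimation, or a harness for studying its behaviour (bias near the score
tails, null safety under no treatment effect, race-stratified operation).

## Worked example

```r
library(chemothresh)

## a synthetic LN- registry cohort with true threshold theta = 25
gen    <- generate_cohort(synthetic_config(n_patients = 20000, seed = 101))
cohort <- apply_eligibility(gen$cohort, eligibility_preset("ln_neg"))

fit <- chemo_benefit(cohort,
                     rsf_config(n_trees = 200, seed = 42),
                     n_iter = 10, fraction = 0.70)
summary(fit)
```

```
Chemotherapy-benefit threshold model (counterfactual survival forest)
  n = 20000 patients; 200 trees; 10 x 70% subsample bootstrap
Chemotherapy-benefit threshold (subsample bootstrap)
  median RS 25.29 (IQR 24.66-25.40) over 10/10 crossing iterations
  full-data point estimate: RS 25.40
  10 x 70% subsamples, seeds from master scheme

fold changes versus guideline cutoffs:
1.00-fold more patients above threshold RS 25.29 than above cutoff RS 25 (3046 vs 3046)
3.25-fold more patients above threshold RS 25.29 than above cutoff RS 30 (3046 vs 936)
```

The recovered median sits 0.29 RS units from the generator's true
threshold of 25, well inside the bootstrap IQR. The fold changes compare
patient counts above the estimated threshold with counts above each
guideline cutoff: here the estimate lands between the integer scores 25
and 26, so it selects exactly the RS > 25 population (fold 1.00) and
3.25-fold more patients than the RS > 30 rule. A threshold *below* a
cutoff gives a fold above 1 ("more patients would be offered
chemotherapy"); a threshold above it gives a fold below 1, reported as
"fewer".

Descriptive survival statistics for the same cohort:

```r
fit_cox(cohort, c("risk_group", "race", "age", "chemo"))  # HR table + C-index
chemo_hr_by_group(cohort)   # chemo HR stratified by low/intermediate/high RS
```

and per-race thresholds with pairwise rank tests:

```r
race_specific_thresholds(cohort, rsf_config(n_trees = 200, seed = 42))
```

`run_full_analysis(analysis_config(...))` chains all of the above (cohort
loading or generation, eligibility, summaries, Cox descriptives, threshold
estimation, fold changes) into one seeded, reproducible report.

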