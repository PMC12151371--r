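# adhera

Multi-scale medication-adherence labeling, simulation and prediction from
electronic pill-bottle (MEMS) event logs.

Patients on long-term once-daily oral therapy — e.g. adjuvant endocrine
therapy after hormone-receptor-positive breast cancer — miss doses in
structured ways: adherence is strongly habit-persistent day to day,
weekends disrupt routines, and slowly-changing psychosocial factors
(self-efficacy, symptom burden, treatment arm) shape weekly patterns.
`adhera` is for biostatisticians and behavioral researchers who have
timestamped bottle-opening logs plus periodic surveys and want
leakage-safe predictive models of who will miss their medication
tomorrow, or fall below threshold next week.

## What it computes

**Labels.** A day is *adherent* when its opening falls within 24 ± 6 h of
the previous opening (closed interval `[18, 30]` h, attached to the day
of the later opening; no-event days are non-adherent). A week (a
subject-anchored 7-day block) is adherent when more than 80% of its days
are — ≥ 6 of 7 under a once-daily regimen. The first 30 days of each
record are trimmed (monitoring-awareness inflation). Derived per-week
attributes: weekend adherence level (0/50/100), modal dosing epoch
(Morning/Afternoon/Evening/Night), mean and sd of the dosing hour.

**Features.** Daily model: 7 lagged days × 6 channels (adherence flag,
epoch one-hots, weekend flag). Weekly model: 4 lagged weeks × 11 channels
(weekly flag, weekend-level one-hots, epoch one-hots, hour mean/sd, and a
zero-event-week indicator). Static survey features are availability-
filtered (≥ 60%), alpha-screened (Cronbach ≥ 0.7), imputed (round-robin
regression, fit on train), min–max scaled, and joined to samples by
carry-forward of the latest completed timepoint.

**Model.** A dual-branch fusion classifier: an LSTM (implemented from
first principles, gradient-checked) reads the lagged tensor; a dense
layer reads the static vector; the concatenated hidden states pass
through dropout, a dense hidden layer and a sigmoid output, trained with
Adam, binary cross-entropy and patience-5 early stopping. Baselines —
random forest, SVM, gradient-boosted trees, logistic regression — get the
identical flattened feature set.

**Evaluation.** Subject-level nested 5-fold cross-validation: imputation,
scaling, SMOTE (hand-rolled nearest-neighbor interpolation) and
L1-based feature selection with lag expansion are all fitted inside the
training fold; disjointness of train/test subjects is asserted at every
fit. Metrics are accuracy / precision / recall / specificity (adherent =
positive, so specificity measures non-adherence detection), mean ± sd
over folds. Feature importance uses expected-gradient attributions,
averaged over folds (`explain_cv`).

**Simulation.** `generate_cohort()` plants recoverable structure — a
persistence-ρ Markov chain on daily states, weekend shift, initial
high-adherence window, regular/irregular dosing-time archetypes, and a
static covariate linked to adherence — so every stage is testable without
patient data. `recover_persistence()` inverts pooled flip rates (with an
analytic autocorrelation correction) to recover the planted ρ.

## Worked example

```r
library(adhera)

coh    <- generate_cohort(cohort_params(n_subjects = 20, n_days = 150, seed = 42))
cfg    <- default_config(seed = 42)
labels <- label_cohort(coh$events, cfg)

head(labels$daily[labels$daily$subject_id == "S001", ], 3)
#>   subject_id       date has_event event_hour inter_dose_hours is_adherent
#> 1       S001 2021-02-24         1   9.233333         24.21667           1
#> 2       S001 2021-02-25         1   9.283333         24.05000           1
#> 3       S001 2021-02-26         1   9.350000         24.06667           1
#>     epoch is_weekend
#> 1 Morning          0
#> 2 Morning          0
#> 3 Morning          0

samples <- build_task_samples(labels, coh$survey, "daily", cfg)
samples
#> <adhera_samples: 2157 daily samples, 7 lags x 6 channels, 7 static features>

report <- run_nested_cv(samples, c("fusion", "logistic_regression"), cfg)
report
#> <adhera_cv_report: daily task, 5 folds, majority rate 79.4%>
#>   fusion                   acc  94.5+/- 1.2  prec  95.1  rec  98.0  spec  72.9
#>   logistic_regression      acc  93.0+/- 5.0  prec  94.9  rec  96.5  spec  71.4

recover_persistence(labels$daily)
#> [1] 0.847
```

Reading the output: each subject's mornings around 09:15 with ~24 h gaps
are adherent days; 2,157 day-level samples carry a 7 × 6 dynamic tensor
plus 7 static survey features each. Both models beat the 79.4% majority
rate because yesterday's state is highly informative (the planted
persistence, recovered here as ρ̂ = 0.847 against a true 0.85); the
fusion model's higher specificity means it catches more of the
non-adherent minority days. `explain_cv(samples, cfg)` then ranks
features by mean absolute attribution — on cohorts like this the lag-1
adherence flag tops the daily ranking while the planted static covariate
surfaces only in the weekly model's top features.

A command-line front end wraps the same functions:

```sh
adhera run --config inst/extdata/demo-config.yaml --out demo_run/
```

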