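---
title: "Multi-scale medication adherence modeling with adhera"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale medication adherence modeling with adhera}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patients on long-term once-daily oral therapy — the motivating setting is
adjuvant endocrine therapy after hormone-receptor-positive breast cancer —
frequently drift away from their prescribed regimen, and the drift is
dynamic: a missed dose today raises the odds of a missed dose tomorrow,
weekends disrupt routines, and slowly-changing psychosocial factors
(self-efficacy, symptom burden, social support) shape the broader trend.
Electronic pill-bottle monitors (MEMS) timestamp every bottle opening and
make this behavior observable at the single-dose level.

`adhera` turns raw opening timestamps into daily and weekly adherence
labels, builds lagged dynamic features and survey-derived static features,
and fits a dual-branch classifier that predicts the next day's (or week's)
adherence, with classical baselines, inside a subject-level nested
cross-validation harness designed so that no information can leak from
test subjects into any fitted transform.

## Labels

**Daily adherence.** A day with an opening is adherent when the interval
since the previous opening lies in the closed window 24 ± 6 hours
(`[18, 30]` h). The flag is attached to the calendar day of the *later*
opening; a day with no opening is non-adherent. Labeling starts the day
after a subject's first post-trim event (the first event only seeds the
interval) and runs through the last event day, so device-silent gaps in
between become explicit non-adherent days. The window endpoints are
inclusive — the permissive reading of "within 24 ± 6 hours" — and widening
the window can only turn event-days adherent, never the reverse (a tested
invariant). Days on which the device is missing are indistinguishable from
missed doses and are labeled non-adherent; the opening record is the only
ground truth available.

**Weekly adherence.** Each subject's labeled days are cut into consecutive
7-day blocks anchored at the first labeled day (a trailing partial week is
dropped; the original study does not fix a calendar convention, and
subject-anchored blocks avoid ragged first weeks). A week is adherent when
more than 80% of its days are adherent, which under a once-daily regimen
means at least 6 of 7. Each week also carries: the weekend adherence level
(0/50/100, from the number of adherent Saturday/Sunday days), the modal
dosing epoch (Morning [06–12), Afternoon [12–18), Evening [18–24),
Night [00–06), ties broken Morning > Afternoon > Evening > Night), and the
mean and standard deviation of the dosing hour over the week's event days.
The hour statistics are plain arithmetic mean/sd by default; a circular
alternative (`circular_time = TRUE`) exists for regimens that straddle
midnight, but once-daily evening/morning regimens rarely do, so it is off
by default. A single-event week has `time_std = 0`; a zero-event week has
no time statistics at all and is flagged (see below).

**Observation-effect trim.** The first 30 days of each subject's device
record are discarded before labeling (`hawthorne_trim_days`): adherence in
the first weeks of monitoring is typically inflated by the awareness of
being observed, and early records also contain device-adjustment
artifacts.

## Features

The daily model sees, for each of the 7 days before the target day
(`daily_lag`), six channels: the adherence flag, four epoch one-hots, and
the weekend flag — a 7 × 6 tensor per sample. The weekly model sees, for
each of 4 prior weeks (`weekly_lag`), eleven channels: the weekly
adherence flag, three weekend-level one-hots, four modal-epoch one-hots,
the two hour statistics, and an indicator marking zero-event weeks whose
hour statistics are absent. The indicator is the package's answer to an
ambiguity: a zero-event week has no dosing hour, yet the recurrent branch
needs a rectangular tensor. The absent values are left `NA` at build time
and filled with the *training-fold* channel means when a model is fitted,
with the indicator telling the model which values are real. Lag axes run
oldest to newest everywhere.

Static features come from per-subject, per-timepoint survey scores
(baseline / 4-month / 8-month). The package ships a generic scoring engine
(`score_scales`): each scale declares its items, reverse-coded items (
mapped as `max + min − x` on the item's stated range), and sum or mean
aggregation; scales may be screened by Cronbach's alpha at a 0.7 cutoff.
Item-level scoring keys for specific commercial instruments are out of
scope. Features must be at least 60% non-missing (computed on training
subjects; the boundary is kept at ≥) to enter the models. Remaining
numeric missingness is filled by round-robin regression imputation —
each incomplete column repeatedly re-estimated by least squares from all
others, models fitted on training rows only — categorical missingness by
training mode followed by one-hot expansion, and all numeric features are
min–max scaled to the training fold's [0, 1]. Survey timepoints are joined
to samples by carry-forward: each sample gets the most recent timepoint
completed at or before its target date (baseline before the 4-month
follow-up completes); carry-forward is the only causally valid temporal
join.

## The fusion model

The classifier mirrors the two kinds of input. The dynamic tensor feeds a
single LSTM layer (16 units by default) whose final hidden state
summarizes the recent behavioral trajectory; the static vector feeds one
dense ReLU layer (8 units). The two hidden states are concatenated,
passed through dropout (rate 0.2, active only in training), one dense
ReLU layer (8 units), and a sigmoid output trained with binary
cross-entropy and Adam (learning rate 0.01, batch 64). Training holds out
15% of the training fold for early stopping: when the validation loss has
not improved for 5 consecutive epochs, training halts and the best-epoch
weights are restored; the epoch cap is 40. The LSTM, its
backpropagation-through-time, Adam, dropout and the attribution gradients
are implemented from first principles in base R and verified against
central finite differences in the test suite. The classification
threshold is fixed at 0.5; the positive class is *adherent*, so
specificity measures detection of non-adherence, the clinically critical
minority. Hidden sizes, optimizer and batch size are config-exposed
defaults, not claims about any published setting.

Baselines — random forest, RBF-SVM, gradient-boosted trees, logistic
regression — consume exactly the same feature set flattened to
`lag{i}_{channel}` columns plus the static block, so the comparison is
between architectures, not feature sets.

## Evaluation pipeline

Cross-validation is subject-level: subjects (not samples) are shuffled and
partitioned into 5 near-equal test sets, so a subject's rows never appear
on both sides of a fold. Within each outer training fold, in order:
imputation and scaling are fitted; SMOTE balances the classes by convex
interpolation between minority nearest neighbors on the flattened
representation (synthetic rows are re-inflated to tensor form for the
recurrent branch); then an L1-penalized logistic model (penalty chosen by
internal cross-validation) selects features, and any dynamic channel
selected at one or more lags is retained at *all* lags so the tensor
stays rectangular. SMOTE precedes selection, matching the processing
order of the study pipeline this package operationalizes. When a
hyperparameter grid has more than one combination, an inner subject-level
grid search on the outer training fold picks the winner; default grids
are single combinations, chosen to keep the demo pipeline fast. Every
fitted transform asserts at run time that its fitting subjects are
disjoint from the fold's test subjects. Metrics (accuracy, precision,
recall, specificity, as percentages) are computed from stored confusion
counts — undefined ratios are reported missing, never zero — and
aggregated as mean ± sd over folds.

One deliberate simplification: the inner tuning loop reuses the outer
training fold's preprocessing rather than re-fitting imputer/scaler
inside every inner fold. Inner folds are drawn entirely from outer
training subjects, so outer test data remain untouched; the shortcut only
makes inner-loop estimates slightly optimistic relative to a fully nested
re-preprocessing, which affects hyperparameter choice, never reported
metrics.

## Attributions

Feature importance uses expected gradients, a gradient-based additive
attribution: for a sample `x`, background reference `b` and
`α ~ U(0, 1)`, the contribution of feature `i` is
`(x_i − b_i) · ∂f/∂x_i` evaluated at `b + α(x − b)`, averaged over a
seeded background drawn from the data. Per feature the report gives the
mean signed attribution (direction of association with adherence) and the
mean absolute attribution (importance). `explain()` attributes one
trained model; `explain_cv()` refits the fusion model per
cross-validation fold and averages the per-fold attribution tables, which
is the default reporting mode — single-fit attribution ranks on
cohort-sized data are noticeably noisier, and fold-averaging stabilizes
them without touching held-out data (each fold's attributions use only
that fold's training subjects).

## The synthetic cohort generator

No patient data ship with the package; every downstream stage is
exercised on simulated cohorts with planted, recoverable structure. The
generator is deliberately the simplest process that reproduces the
phenomena the pipeline is built to detect:

- **Habit persistence**: daily taken/missed states follow a two-state
  Markov chain — with probability ρ (default 0.85) the subject repeats
  yesterday's state, otherwise a fresh state is drawn from her adherence
  probability. ρ is recoverable from event logs by a pooled flip-rate
  inversion whose plug-in denominator is corrected analytically for
  Markov autocorrelation (`recover_persistence`).
- **Weekend disruption**: the daily miss probability is shifted additively
  by δ_w (default 0.10) on Saturdays and Sundays.
- **Monitoring-awareness window**: for the first 30 days the miss
  probability is multiplied by 0.3, emulating the early high-adherence
  phase that motivates the trim.
- **Dosing-time archetypes**: 60% of subjects are "regular" (jitter sd
  0.35 h around a preferred hour), 40% "irregular" (sd 2.5 h), mirroring
  the observed contrast between clock-regular and erratic dosers.
- **Static linkage**: one simulated scale (`adh_selfeff`, coefficient 1.5
  per SD on the daily log-odds) and the intervention arm (`group`, 0.4)
  shift each subject's adherence probability; four further scales are
  pure distractors. Because the link is constant within subject, its
  signal is strongest at the weekly scale, where lagged weekly flags
  summarize propensity only coarsely — the multi-scale asymmetry the
  attribution tests look for.
- **Surveys**: three timepoints per subject, scores centered on the
  subject's latent trait with small occasion noise, 5% of cells missing
  completely at random.

Defaults (32 subjects, 240 days) match the scale of the monitored-cohort
study design this tooling targets; they were fixed once, from that
design, and are not adjusted per experiment. What the generator does
*not* emulate: informative missingness, survey response styles,
mid-study behavior change, multi-dose regimens, or treatment
discontinuation — so green tests demonstrate pipeline correctness and
recoverability of planted structure, not clinical performance on real
cohorts.

## Numerical and degenerate-input choices

- Timestamps are timezone-naive local clock times truncated to the
  minute; daylight-saving discontinuities are ignored (the signal of
  interest is the local clock hour). Same-minute duplicate openings
  collapse to one event (device chatter).
- Constant features min–max scale to 0 with a warning; constant training
  columns in the L1 selector are simply never selected.
- An empty feature selection falls back to all features with a warning.
- SMOTE reduces its neighbor count with a warning when the minority class
  is smaller than k + 1 (default k = 5).
- Cronbach's alpha is undefined at zero total-score variance; such scales
  are excluded with a warning.
- The fusion net aborts with a diagnostic on a NaN loss rather than
  returning a silently broken model.
- Problem sizes in the test and acceptance suites (cohorts of 8–50
  subjects, 80–240 days, epoch caps in the tens) are chosen so the whole
  suite runs in minutes on one CPU core while leaving every planted
  effect comfortably detectable.

## Known limitations

Device non-wear is unidentifiable from non-adherence; the weekly hour
statistics assume doses do not straddle midnight unless circular mode is
on; the generator's linear-logistic static link cannot represent
interactions between static and dynamic factors; and the fusion model's
small default capacity is sized for cohort-scale data (tens of subjects),
not for large registries.
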