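---
title: "Methods: static and dynamic multi-task prediction of substance-use initiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: static and dynamic multi-task prediction of substance-use initiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dynmtl)
```

This vignette is the package's account of its science: the two modeling
frameworks, the censoring-aware labeling they rest on, the synthetic cohort
used to exercise them, the numerical and design choices that were genuinely
open, and the limits of what the included experiments demonstrate.

## Outcomes, censoring and labels

Initiation of each substance (alcohol, nicotine, cannabis, and the derived
"any substance") is a time-to-event outcome: an event indicator plus an
event-or-censoring time, recorded as absolute age in months and converted
to follow-up time by subtracting baseline age (`convert_event_times()`;
times are rounded to micro-month precision so that boundary comparisons of
times computed as differences of recorded ages are exact).

The static framework needs a binary label at a fixed horizon *H* (48 months
in the primary analysis). `make_horizon_labels()` applies the rules:
initiation before *H* is positive; remaining initiation-free through *H*
(including initiation after *H*) is negative; censoring before *H*, or
missing event information, leaves the label **unobserved**, encoded in a
mask `m_it`. Masked cells contribute nothing to losses or metrics anywhere
in the package — this is the single most important invariant of the design,
and it is tested by brute-force oracles. Subjects with no observed label on
any task leave the analytic set.

A boundary convention follows from discrete-time semantics: the synthetic
generator records an event occurring within an interval at the interval's
*end*, so an event in the interval ending exactly at *H* is
horizon-negative (time ≥ *H*) while its interval label is positive. The
person-period-to-horizon consistency property is therefore stated for
events in intervals ending strictly before *H*.

## Person-period expansion

`expand_to_person_periods()` turns longitudinal records into one row per
subject per interval, with intervals defined by consecutive visits as
half-open `(start, end]` windows. Features come from the interval's *start*
visit, so every predictor is known before the outcome it predicts —
choosing the end visit would leak the outcome into the features. Interval
start and end enter as numeric predictors. After a task's event the subject
leaves that task's risk set (later intervals masked); an interval reaching
past the censoring time is masked for all tasks. Single-visit subjects
contribute one interval of configurable width (default 12 months).

## The two objectives

Static (fixed-horizon) training minimizes the task- and class-weighted
masked binary cross-entropy with logits: per task, the mean over observed
subjects, weighted by `α_t`, with `pos_weight_t` multiplying the
positive-class term. The default `pos_weight_t` is the observed
negative/positive ratio on the training split; all weights are tunable, and
the tuned desk-scale configuration below uses `pos_weight = 1` (selected on
the validation objective). Dynamic training minimizes the unweighted mean
of the same cellwise loss over all observed interval × task cells — the
printed form of the dynamic objective carries no weights, and the package
keeps it that way by default while exposing weighting as an option.

Two reductions are verified numerically in the tests: the weighted loss
equals the plain loss when `α_t = Σ_i m_it / Σ_{i,t} m_it` and
`pos_weight = 1`, and both losses match scalar double-loop oracles to
1e-10 on random instances covering every mask pattern.

## Networks and training

Both frameworks use a shared fully connected trunk (ReLU, dropout) with
either a joint linear output layer (one logit per task) or per-task adapter
heads (a small ReLU bottleneck, default width 32, plus a linear unit —
the adapter dimensions were an open choice). The networks, backpropagation,
Adam (with L2 weight decay folded into the gradient, matching the common
coupled implementation), global gradient-norm clipping (default 5.0) and
early stopping are implemented in base R on BLAS matrix operations;
gradients are verified against finite differences for both head types.

Early stopping monitors, per framework: the mean over tasks of
(AUROC + PR-AUC)/2 on validation for the static pathway (tasks with
single-class validation labels are skipped — the combination formula was an
open choice), and the masked validation loss for the dynamic pathway. The
best-epoch parameters are restored. Every stochastic step (initialization,
shuffling, dropout, permutation, bootstrap, search) takes a seed, and
training is single-threaded, so runs are exactly reproducible.

Hyperparameter search (`tune()`) offers random sampling and an
independent-factor Tree-structured Parzen Estimator: completed trials are
split into a good fraction (γ = 0.25) and the rest, each parameter is
modeled with Parzen kernel densities l(x) and g(x) (categoricals with
smoothed frequencies), and candidates drawn from l are scored by l/g.
Median pruning is not implemented.

The desk-scale model configurations used by `run_config()` were selected
once on the validation objective (never on test metrics): static —
MLP(64, 32), dropout 0.2, learning rate 1e-3, weight decay 1e-4, batch 256,
up to 100 epochs, patience 10, `pos_weight = 1`; dynamic — MLP(64, 32),
dropout 0.1, learning rate 5e-4, weight decay 1e-3, batch 512, up to 120
epochs, patience 12. The wider 256/128 trunk performs equivalently here but
trains several times slower; on a linear generating process added capacity
cannot pay for itself.

## Baselines, preprocessing and splitting

The single-task baseline is L2-regularized logistic regression via
`glmnet` (ridge, per task, on rows with an observed label), with the
penalty chosen by seeded 5-fold cross-validation unless fixed explicitly.

Preprocessing is strictly train-fitted (`fit_preprocess()`): numeric
coercion, removal of columns entirely missing after coercion, median
imputation from training rows (columns with no observed training values
fall back to 0), then z-scoring with training means and SDs; zero-variance
columns get divisor 1. The identical state transforms validation and test
data, and the tests assert the state is invariant to arbitrary modification
of non-training rows. Splitting is a single seeded permutation of subject
IDs cut at 70 / 85%, so the three sets partition the subjects exactly and
no subject contributes intervals to two sets.

## Evaluation

Interval-level and subject-level discrimination (AUROC as the tie-averaged
rank statistic; PR-AUC as step-wise average precision, chosen over
trapezoidal interpolation because the latter is optimistic under class
imbalance) and calibration (Brier; ECE over 10 equal-width bins — the bin
count was an open choice and is configurable; reliability curves) are
computed over observed cells only. Subject-level cumulative risk multiplies
survival across a subject's observed intervals in log space (probabilities
clamped at 1 − 1e-12), agreeing with the direct product to 1e-12.
Confidence intervals resample *subjects* with replacement (default
B = 2000) and take the 2.5th/97.5th percentiles; degenerate resamples are
skipped and counted.

One structural caveat the package surfaces deliberately: because subjects
leave the risk set at their event, initiators accumulate cumulative risk
over fewer observed intervals than never-initiators. When interval-level
discrimination is moderate, this truncation can dominate the product-form
cumulative risk and depress subject-level AUROC below the interval-level
value — on the synthetic cohort it does. The framework comparison tables
therefore use interval-level AUROC for the dynamic models (the level at
which the dynamic ridge baseline is defined), and the subject-level
cumulative-risk evaluation is reported as its own table.

## The synthetic cohort

`generate_cohort()` draws per-interval initiation from the discrete-time
hazard

logit h_ik^t = c_t + Σ_j β_tj x_ij(k) + λ_t u_i + γ z_i(k) + s_site(i)

with a standard-normal shared liability u_i, a stationary AR(1)
time-varying exposure z, and exposures x_j(k) that themselves evolve as
AR(1) processes (temporal stability 0.6, a realistic year-to-year
stability for behavioral instruments). Eight signal exposures carry effects
of 0.10–0.40 per SD, shared in direction across substances (rare tasks
scaled by 0.9) to encode common liability; 20 null exposures carry zero
effect; alcohol loads weakly on sex, nicotine on its polygenic score (0.30)
— mirroring the observation that nicotine-specific genetic risk matters for
nicotine only. Twenty-one sites get small random intercepts (SD 0.1);
20 ancestry PCs and 4 polygenic scores are standard-normal stand-ins.

Defaults emulate a large adolescent cohort: 10,000 subjects, five visits at
12-month spacing (so four hazard intervals spanning the 48-month horizon),
baseline age 119 ± 7.4 months, per-interval dropout probability 0.01
(≈ 3–4% censored before the horizon), 15% of null columns fully missing
(exercising the drop-all-missing rule without destroying ground truth
needed by recovery tests) plus 2% sporadic cell missingness. The per-task
intercepts are the output of `calibrate_intercepts()` — bisection of the
closed-form expected prevalence over a large simulated covariate sample —
against targets of 36.5% (alcohol), 5.44% (nicotine) and 3.42% (cannabis),
and are frozen as defaults. The "any" outcome is derived as the earliest
substance event, never simulated separately, which guarantees internal
consistency. Events are recorded at interval end; dropout is recorded
mid-interval.

What the generator does *not* emulate: real instrument scales and their
drift, nonlinear and interaction effects, informative (outcome-dependent)
censoring, site-by-covariate structure, and genotype realism beyond
Gaussian scores. Because the hazard is exactly linear in the observed
features, the single-task ridge baseline is a *correctly specified* model
here — a deliberately hard benchmark for the networks. Passing tests on
this cohort demonstrate that the machinery (labeling, masking, losses,
training, aggregation, importance) behaves correctly and that temporal
information is exploited; they do not demonstrate that multi-task networks
beat well-tuned single-task baselines on real, messier data, where
nonlinearity and noisy high-dimensional features are exactly what a shared
trunk exploits. Consistent with that, in the included experiments the
network-vs-ridge PR-AUC comparison on the rare outcomes goes either way
across seeds, while the dynamic-vs-static advantage is large and stable.

## Experiment sizes in the test suite

The acceptance experiments run at sizes chosen to keep the full suite in
the tens of minutes on one CPU while leaving clear statistical margins:
the framework comparison trains all four model cells on five replicate
cohorts of 8,000 subjects (seeds 0–4); importance recovery uses the
dynamic ridge model for the any-substance task on 20 cohorts of 20,000
subjects with 8 permutation repeats (at this size the minimum signal
importance exceeds the maximum null importance by ~5× in a typical seed;
the ridge model is used as the probe because network shrinkage of the two
weakest signals — 0.10/SD — says more about regularization than about the
generator); calibration sanity draws 50,000 labels from a trained
network's own predicted probabilities, where ECE < 0.01 and the Brier
score matches its analytic expectation E[p(1−p)] to 1e-3.

## Known limitations

* No GPU or multicore path; the networks are deliberately desk-scale.
* No recurrent/attention architectures or explicit time-to-event
  likelihoods; risk dynamics enter only through person-period expansion and
  numeric time predictors.
* Cox and marginal-structural comparators are not fit here; their rankings
  are ingested from two-column files for the concordance analyses.
* Dynamic-pathway missing exposures are median-imputed, not carried
  forward; with block-missing columns this is equivalent, but for sporadic
  missingness carry-forward would be a defensible alternative.
* The permutation-importance pre-screen (first-layer weight norms or
  |coefficients| when `max_features` caps the evaluated set) is an
  approximation: a feature influential only through late layers could be
  screened out.
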