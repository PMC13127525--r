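# dynmtl

Static and dynamic multi-task prediction of adolescent substance-use
initiation.

## The problem

Substance-use initiation (alcohol, nicotine, cannabis) is a time-to-event
process unfolding across adolescence. Risk factors span many domains, are
partly shared across substances, and change over time; two of the four
outcomes of interest are rare (a few percent), and follow-up is right-censored
for part of any cohort. `dynmtl` implements a complete prediction system for
this setting, built around two complementary frameworks:

* a **baseline (static) multi-task model** that predicts initiation within a
  fixed horizon *H* (48 months) from one record per participant, and
* a **dynamic discrete-time multi-task model** that predicts per-interval
  initiation risk on person-period (participant × interval) data and
  aggregates it into subject-level cumulative risk.

Both frameworks share a multilayer-perceptron trunk with task-specific
outputs for the four outcomes (alcohol, nicotine, cannabis, any substance)
and are trained with masked losses so that a participant contributes to a
task only where that task's label is observed.

The package is aimed at biostatisticians and epidemiologists working with
longitudinal youth cohorts (the data layout mirrors large studies such as
ABCD, whose actual data are restricted-access and are **not** included);
everything here runs end-to-end on a built-in synthetic cohort generator
with known ground truth.

## The model

Labels. For horizon *H*, subject *i* and task *t*: `y_it = 1` if initiation
occurred before *H*, `y_it = 0` if the subject remained initiation-free
through *H*, and the label is **unobserved** (`m_it = 0`) when the subject
was censored before *H* — censored subjects contribute nothing for that
task.

Static objective (task- and class-weighted masked cross-entropy):

    L = Σ_t α_t · (Σ_i m_it)⁻¹ · Σ_i m_it · BCEWithLogits(z_it, y_it; pos_weight_t)

Dynamic objective (unweighted mean over observed interval × task cells):

    L = Σ_{i,t} m_it · BCEWithLogits(z_it, y_it) / Σ_{i,t} m_it

Subject-level cumulative risk from interval probabilities p_k:

    CumRisk = 1 − Π_k (1 − p_k)

Single-task L2-regularized (ridge) logistic regressions provide the
comparison baseline in both frameworks. Evaluation covers AUROC, PR-AUC
(emphasized for the rare outcomes), Brier score, expected calibration error
and accuracy, with subject-level bootstrap confidence intervals. Feature
importance uses permutation importance (drop in AUROC), and cross-model
agreement is quantified by Jaccard overlap of top-k feature sets and an
inverse-rank consensus score over features identified by every model.

## Worked example

```r
library(dynmtl)

config <- run_config(cohort = cohort_config(n_subjects = 8000, seed = 1),
                     split_seed = 1)
res <- run_study(config)
res$tables$delta
```

which prints (AUROC; `mtl_*` is the multi-task network, `lr_*` the ridge
baseline; dynamic values are interval-level):

```
      task mtl_static mtl_dynamic    mtl_delta lr_static lr_dynamic   lr_delta
1  alcohol  0.6317771   0.6906495  0.058872353 0.6464313  0.7101867 0.06375538
2 nicotine  0.6024141   0.6055444  0.003130278 0.5976993  0.6376188 0.03991949
3 cannabis  0.6336934   0.6229614 -0.010731957 0.6043804  0.6530889 0.04870849
4      any  0.6331585   0.6794702  0.046311667 0.6414033  0.6971477 0.05574442
```

On the synthetic cohort the dynamic models outperform their static
counterparts for almost every task and seed — temporal information, not
model family, is the dominant driver of performance, and the per-seed deltas
(about +0.05 for the common outcomes) sit in the range reported for real
adolescent cohorts. `res$tables$static` and `res$tables$dynamic` hold the
network-vs-ridge comparisons within each framework,
`res$tables$dynamic_subject` the subject-level cumulative-risk evaluation,
`res$importance` the per-task permutation-importance rankings, and
`res$concordance` the Jaccard/consensus agreement between the static and
dynamic rankings (external rank lists, e.g. from Cox models fit elsewhere,
can be supplied via `run_config(interp = list(rank_files = ...))`).

The synthetic generator is calibrated so that end-of-follow-up prevalences
match a realistic adolescent cohort: ~36.5% alcohol, ~5.4% nicotine, ~3.4%
cannabis, ~40% any substance, with a few percent of subjects censored before
the 48-month horizon.

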