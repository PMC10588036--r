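---
title: "Risk stratification with hazard-ratio splitting trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk stratification with hazard-ratio splitting trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrcart)
```

## The problem

In severe systolic heart failure with central sleep apnea, the question is
not only *whether* a patient will reach a composite endpoint (death,
lifesaving cardiovascular intervention, or unplanned heart-failure
hospitalization) but *at what average rate*. `hrcart` stratifies a
time-to-event cohort into subphenotypes — terminal nodes of a binary
decision tree — each summarized by an incidence rate (IR, events per 100
patient-years) and a hazard ratio against the lowest-risk node. A
circulating-miRNA marker (e.g. plasma miR-133a-3p relative to the
miR-486-5p internal standard) can enter the tree alongside clinical
covariates and NT-proBNP, and its incremental prognostic value over
nested clinical Cox models is quantified with the c-index, the continuous
NRI and the IDI.

## The splitting criterion

Standard survival CART (e.g. `rpart` with exponential scaling) splits on
deviance. Here the split score is taken directly from the effect measure
clinicians read: for a candidate binary split ("value $\le c$ goes left")
the univariate Cox model of the right-side indicator within the node gives
a log hazard ratio $\hat\beta$ with standard error $s$, and the candidate's
score is the Wald statistic

$$ \chi^2_W = (\hat\beta / s)^2 . $$

We maximize $\chi^2_W$ rather than $|\hat{\mathrm{HR}}|$ itself: the raw
HR is maximized by carving off tiny extreme groups, while the Wald
statistic is monotone in $|\hat\beta|$ at fixed precision and so balances
effect size against the information in each child. A split is made only
when the winning candidate's p-value (from $\chi^2_1$) beats
`alpha_split`, ties broken by smaller p, then variable name, then smaller
cutoff — making the fit invariant to row order. Cox fits use the Efron
tie correction throughout.

Growth parameters (all in `tree_params()`): `max_depth = 3` (at most
eight terminal nodes), `min_node_n = 30`, `min_node_events = 5`,
`alpha_split = 0.05`. The event floor is set at 5, not higher: in a
cohort of ~600 with ~3 years of follow-up, a genuine low-risk leaf at
IR ≈ 5/100 py holds ~40 subjects and only ~5–6 events, and a stricter
floor would make exactly the clinically interesting low-risk split
inadmissible. Candidate cutoffs are exhaustive midpoints between
consecutive distinct values; `max_cutpoints` thins them evenly (the
thinned set is always a subset of the exhaustive one), which we use for
bagging where thousands of trees are grown.

There is no pruning beyond the significance/size stopping rule, and no
surrogate splits: a subject missing a split variable is excluded from
that node's split fit and is reported unassignable at prediction.

One calibration caveat, verified by the test suite: the "(1 − α) of null
datasets yield a root-only tree" property holds for a *single* candidate
split (one binary variable). With many variables and cutoffs the maximum
of many Wald statistics is selected, so the root splits more often than
α under the null — the usual CART selection effect. The null-calibration
experiments therefore use one binary noise covariate.

## Node metrics

* **IR** per node: $100 \cdot d_i / \mathrm{py}_i$ with person-years the
  summed observed follow-up.
* **Node HRs**: one Cox fit on terminal-node indicators, reference = the
  node with the lowest IR (HR ≡ 1). Non-estimable HRs (zero-event nodes)
  are flagged `NA`.
* **IRV**: $(1/N)\sum_i n_i\,|IR_i - IR|$ with $IR$ the *pooled*
  population rate (total events over total person-years, not the
  n-weighted mean of node rates). Zero iff all node rates equal the
  pooled rate; units are events per 100 patient-years.
* **Risk bands**: nodes grouped by HR against edges 2 / 5 / 10 into low,
  intermediate, high and very high — reproducing the familiar four-band
  pattern (reference ≈ 1; ~2–4; ~6–7; ~12). Edges are configurable.
* **iAUC**: the cumulative/dynamic AUC(t) — cases have events by t,
  controls are still under observation after t — estimated with IPCW
  weights from the censoring-distribution Kaplan–Meier (a naive
  unweighted mode is kept for cross-checks), evaluated at the event times
  inside the window (default 0.25 to 5 years; "3 months" is read as
  0.25 y exactly) and averaged with weights proportional to the
  Kaplan–Meier event mass at each time (uniform weighting available).
  The marker for tree evaluation is the *ordinal node risk*, i.e. the
  node rank by IR; ranking by IR rather than HR is a choice — the two
  orders coincide in all our simulations — and the node IR itself can be
  used instead.

## Incremental marker value

Nested clinical models: model 1 = treatment arm, age, sex; model 2 adds
the SBP < 120 mmHg flag, diabetes, diuretic, atrial fibrillation,
cardiac device and 6-min walk distance; model 3 adds log(NT-proBNP).
Marker HRs are reported per one unit of the analysis scale (natural-log
relative units; a per-SD option exists because published HRs of this kind
often leave the increment implicit).

`cnri_idi()` computes the continuous NRI and IDI at a 2-year horizon from
each model's Breslow-baseline predicted event probabilities, with
case/control status weighted by inverse-probability-of-censoring weights.
Confidence intervals come from perturbation resampling (default 300
replicates of i.i.d. Exponential(1) subject weights, refitting both
models and the censoring KM per replicate). The estimator is exactly
antisymmetric under swapping the models, and exactly zero when the
models coincide. `delta_cindex()` uses a paired subject-level bootstrap.

Natural logarithm everywhere: with NT-proBNP around a median of
1400 pg/mL, ln gives ~7.2, making a cutoff of 6 (~403 pg/mL) clinically
sensible, whereas log10 would not.

## The synthetic cohort

No patient-level data ship with the package; every experiment runs on a
generator whose defaults emulate the study conditions: n = 587, ~53%
event rate, administrative censoring uniform on [0.5, 5.5] years plus
exponential dropout at 0.02/y (mean follow-up ≈ 3 y), Table-1-style
covariate marginals (age 69.5 ± 9.8, ~90% male, NT-proBNP lognormal with
median 1400 pg/mL, miRNA relative level lognormal with median 1.5
arbitrary units), and a weak negative rank correlation (ρ = −0.167)
between the miRNA and the peptide induced by Iman–Conover-style
reordering, which preserves the marginals exactly.

Follow-up is generated from a *planted* tree-structured hazard:
piecewise-constant (exponential) within each terminal node, which keeps
incidence rates analytically checkable (events/person-years estimates the
node hazard). The default truth has 7 leaves — peptide at the root
(log NT-proBNP ≤ 6), the miRNA (1.5 units) carving the lowest-risk leaf
on the low-peptide side, then walk distance, diabetes and the SBP flag —
with hazards 0.05–0.70/y (IR 5–70 per 100 py) chosen by closed-form
event-fraction calculation to give ~53% events overall. Per-node sizes
of the original study tree are not published, so the planted truth is
explicitly synthetic plumbing, not a reconstruction.

The recovery benchmark (`two_level_spec()` / `two_level_truth()`) is a
separate, deliberately well-powered design: a balanced peptide root split
and a miRNA split on the low side, HR 4 per split with leaf hazards
0.40/0.10/0.80 so each leaf accrues enough events for the change-point
estimate (which converges at cube-root rate) to land within 0.25 SD of
the truth in well over 90% of seeds at n = 600.

What the generator does **not** emulate: treatment-covariate
interactions, time-varying hazards within nodes, informative censoring,
measurement drift between qPCR plates, or any polysomnography dynamics —
covariates are static baseline values. Passing tests therefore show the
estimators are correct under the stated model, not that the original
cohort's numbers are reproduced; the published headline values (e.g. an
iAUC of 0.758) depend on data available only on request and are out of
reach of a desk reproduction.

## Numerical choices and problem sizes

* Cox fits: Efron ties, Newton iteration (`survival`), complete cases
  per model; exact collinearity is an error naming the pair; monotone
  likelihood is flagged non-convergent (|β| > 15) rather than silent.
* Wilcoxon: exact enumeration for pooled n ≤ 20 without ties, otherwise
  normal approximation with tie and continuity corrections. Fisher:
  minimum-likelihood two-sided rule. Quartiles: type 7.
* Screening fold change: ratio of arithmetic group means on the linear
  RQ scale, direction stored (a log-scale mode exists since published
  fold-change scales are often unstated); thresholds are ≥ for the fold
  change and < for the p-value.
* Boundary conventions: "≤ cutoff goes left" everywhere (trees and
  planted truths); median-split ties go low.
* Seeds: one top-level seed fans out to per-stage child seeds by fixed
  offsets, so identical configs reproduce byte-identical outputs.
* Default experiment sizes keep a full check suite in minutes on one
  core: bagging B = 50 in the pipeline smoke run (B = 200 in the
  analysis scripts, B = 1000 for a full study-scale run), 100 seeds for
  recovery/calibration sweeps, 150–300 perturbation replicates. Each is
  a parameter, not a constant.

## Known limitations

* The split statistic is configurable in principle only to the Wald form
  here; likelihood-ratio and log-rank scores of the same split are easy
  extensions but are not implemented.
* No competing-risks machinery: the endpoint is a single composite.
* cNRI/IDI perturbation CIs are asymptotic in spirit; at very small n or
  very few events the coverage degrades (the test suite checks n = 600).
* Bagging is used for variable selection and out-of-bag error only;
  there is no forest-style aggregated predictor, by design.
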