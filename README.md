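# hrcart

Survival risk stratification for clinical cohorts with a customized CART
that splits on Cox hazard-ratio statistics, plus the surrounding
biomarker toolchain: RT-qPCR relative quantification and screening
filters for circulating miRNAs, nonparametric baseline statistics,
nested Cox models with incremental-value indices (Harrell's c, cNRI,
IDI), node-level risk metrics (incidence rates per 100 patient-years,
node hazard ratios, the incidence-rate variation index, time-dependent
cumulative/dynamic AUC and its integral), and a synthetic cohort
generator with a planted tree-structured hazard so every stage is
testable without patient data.

The motivating setting is severe heart failure with reduced ejection
fraction and central sleep apnea, randomized to adaptive
servo-ventilation or control, where plasma miR-133a-3p (relative to the
miR-486-5p internal standard) is evaluated as a prognostic biomarker
next to NT-proBNP.

## The model

At a tree node, every candidate split "variable ≤ c goes left" is scored
by the univariate Cox fit of its right-side indicator: with log hazard
ratio β̂ and standard error s, the score is the Wald statistic
χ² = (β̂/s)². The admissible candidate with maximal χ² splits the node if
its p-value beats `alpha_split`; growth stops at `max_depth` (default 3,
≤ 8 leaves) or at the size/event floors. Terminal nodes are summarized by

- IR_i = 100 · events_i / person-years_i,
- HR_i versus the lowest-IR (reference) node from one Cox fit on node
  indicators,
- IRV = (1/N) Σ_i n_i · |IR_i − IR|, the dispersion of node rates around
  the pooled population rate, and
- the iAUC of the ordinal node risk: cumulative/dynamic AUC(t) with IPCW
  censoring weights, integrated over 0.25–5 years with Kaplan–Meier
  event-mass weights.

Incremental marker value on top of nested clinical Cox models
(1: arm, age, sex; 2: + SBP<120, diabetes, diuretic, atrial
fibrillation, cardiac device, 6-min walk; 3: + log NT-proBNP) is
quantified by Δc-index (paired bootstrap) and by IPCW continuous NRI and
IDI at a 2-year horizon with perturbation-resampling CIs.

## Worked example

The `analysis/` scripts run the whole workflow on the default synthetic
cohort (587 subjects, ~53% events, planted 7-leaf hazard spanning IR
5–70 per 100 patient-years):

```sh
Rscript analysis/01_simulate.R   # cohort + planted truth
Rscript analysis/02_screen.R    # RQ -> log -> screening filters
Rscript analysis/03_describe.R  # baseline tables (Wilcoxon / Fisher)
Rscript analysis/04_cox.R       # nested models, delta-c, cNRI/IDI
Rscript analysis/05_tree.R      # tree, bagging, node metrics
```

Stage 5 prints, for the default seed:

```
[1] log_ntprobnp <= 6.111  (HR right/left = 3.9, chisq = 36, p = 2e-09)
  [2] terminal: n = 102, events = 21
  [3] sixmwd <= 293.4  (HR right/left = 0.518, chisq = 29, p = 7.4e-08)
    ...
 node   n events person_years    ir   hr hr_lo hr_hi rank reference
    2 102     21        255.4  8.22 1.00    NA    NA    1      TRUE
    6 113     75        177.7 42.21 5.20  3.20  8.46    4     FALSE
    7  71     52         83.5 62.24 7.79  4.67 13.00    5     FALSE
    8 173     70        383.7 18.24 2.23  1.37  3.63    2     FALSE
    9 128     77        201.9 38.14 4.78  2.94  7.78    3     FALSE
overall IR = 26.8 per 100 py; IRV = 15.48 per 100 py
iAUC (0.25-5 y) of ordinal node risk: 0.704 (0.661-0.749)
retained:  sbp_lt120, sixmwd, log_ntprobnp, log_mir133a
OOB iAUC: 0.668 +/- 0.035
```

Reading: the natriuretic peptide dominates the root (cutoff 6.11 on the
log scale, ≈ 450 pg/mL, planted at 6); the lowest-risk node runs at
8.2 events per 100 patient-years versus 62 in the worst node; the
spread of node rates around the pooled rate (IRV) is 15.5 per
100 patient-years; the ordinal node risk discriminates with an
integrated AUC of 0.70; and bagged selection over 200 bootstrap trees
retains the peptide, walk distance, the SBP flag and the miRNA.

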