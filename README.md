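# ordertrans

Tools for analysing **discontinuous change in psychotherapy** from daily
self-report time series, and for relating it to repeated fMRI measurements.

Psychotherapeutic change often happens in sudden, discontinuous steps
("order transitions" of a self-organizing system) rather than gradually.
The theory predicts that such transitions are preceded by *critical
fluctuations*: a transient burst of instability in the patient's daily
experience. `ordertrans` implements the analysis pipeline built on that
idea:

1. **Dynamic complexity.** For each rating item with theoretical range
   *R*, a window of *m* consecutive days (default *m* = 7) is scored by

   - *fluctuation intensity* `F = Σ_k (a_k/d_k) / (R·(m−1))`, summing
     amplitude-per-step over the maximal monotone runs `k` of the window
     (a run ends at a strict direction reversal; plateaus extend the
     current run), and
   - *distribution degree* `D = 1 − Σ dev / Σ I`, where for every span of
     the sorted window values the shortfall against perfectly even
     coverage of the range (`I_c = c·R/(m−1)`) is accumulated as
     `dev = max(0, I_c − observed span)`.

   The composite `C = F·D ∈ [0,1]` is stamped on the window's last day
   and averaged over items. `C = 0` iff the window is constant; `C = 1`
   needs a full-range alternation every day.

2. **Order-transition detection.** The global maximum of the
   item-averaged complexity curve is the primary transition; additional
   local maxima within 90% of the peak and at least 14 days away qualify
   as secondary transitions.

3. **Interval labelling.** Each interval between consecutive fMRI scans
   is labelled `OT` (contains a transition), `NOT` (patient interval
   without one) or `ISI` (untreated control interval).

4. **ROI contrasts.** Per subject, interval and region of interest (8
   ROIs: CC/SMA, bilateral DLPFC, bilateral insula, bilateral parietal
   cortex, cuneus), the absolute change in significant-voxel counts (and
   in per-patient *weighted percentages*, counts normalised to the
   subject's largest ROI×scan cell) is compared across interval types:
   paired *t* and exact Wilcoxon for OT vs NOT within patients, Welch *t*
   and exact rank-sum for patient-vs-control contrasts, point-biserial
   effect sizes, Type-III interaction ANOVA, BCa bootstrap intervals, and
   inter-ROI correlation structure before vs after the transition.

5. **Synthetic cohorts.** Seeded generators produce rating series with an
   injected transition day preceded by inflated fluctuations, plus matched
   ROI panels — so the whole pipeline is testable against known ground
   truth.

## Worked example

```r
library(ordertrans)

# a 9-patient + 9-control synthetic cohort at the default study conditions
cfg <- run_config(out_dir = "study_out", design = simulation_design(), seed = 7)
res <- run_study(cfg)

# how many inter-scan intervals of each type?
table(res$labels$label)
#> ISI NOT  OT
#>  16  11   9

# the headline contrast: size of activation change, OT vs NOT vs ISI
subset(res$report, scope == "Mean of all" & measure == "voxels")
#> # A tibble: 3 × 11
#>   scope       measure contrast mean_diff     t    df      p_t p_wilcoxon     r   n_1   n_2
#>   <chr>       <chr>   <chr>        <dbl> <dbl> <dbl>    <dbl>      <dbl> <dbl> <int> <int>
#> 1 Mean of all voxels  OT-NOT       4950. 14.0    8   6.59e- 7  0.00391   0.945     9     9
#> 2 Mean of all voxels  OT-ISI       6444. 21.8   14.9 1.01e-12  0.0000411 0.984     9     9
#> 3 Mean of all voxels  NOT-ISI      1494.  3.72  11.7 3.05e- 3  0.0000823 0.681     9     9

# inter-ROI correlation collapses over the course of therapy
res$intercorrelation$first_scan$mean_r   # 0.77
res$intercorrelation$last_scan$mean_r    # 0.07
```

Reading the output: intervals containing an order transition show much
larger activation changes (mean |Δvoxels| difference ≈ 4950 against
patient intervals without a transition, ≈ 6444 against control intervals;
both large effects, point-biserial r > .9 on this synthetic cohort),
while patient non-transition intervals sit close to control intervals —
the signature pattern the pipeline is designed to detect. `study_out/`
contains every intermediate table (complexity curves, detected
transitions, interval labels, change table, contrast report,
intercorrelation summary) plus figures and a provenance block.

Individual stages are plain functions: `load_ratings()`,
`prepare_series()`, `complexity_series()`, `detect_transitions()`,
`label_intervals()`, `weighted_percent()`, `interscan_changes()`,
`contrast_report()`, `mean_intercorrelation()`, `bca_ci()`, …

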