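---
title: "Dynamic complexity and order transitions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic complexity and order transitions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ordertrans)
```

## The problem

Self-organization accounts of psychotherapy hold that improvement is not
incremental: the patient's cognitive-affective pattern destabilizes, passes
through a phase of *critical fluctuations*, and re-forms in a qualitatively
different configuration — an **order transition**. If that picture is right,
two things should be observable: (i) a transient burst of instability in
daily self-ratings shortly before the change, and (ii) disproportionately
large changes in task-related brain activation across the scan interval
that contains the transition.

`ordertrans` implements the complete analysis chain for that question:
windowed **dynamic complexity** of bounded daily rating items, transition
detection at complexity maxima, OT/NOT/ISI labelling of inter-scan
intervals, and the statistical contrasts of ROI-level activation changes
across interval types. Because raw clinical data of this kind are not
publicly deposited, the package also ships seeded generators that emulate
the study design (9 patients, 7 scanned three times and 2 four times, plus
9 untreated controls; 37–65 daily observations each), so every stage can be
tested against known ground truth.

## Dynamic complexity

Daily items are bounded — a 7-point Likert item can only move inside
[1, 7] — so instability must be measured relative to the *theoretical*
range $R$, not the observed variance. For a window
$x_1, \dots, x_m$ (default $m = 7$ days):

**Fluctuation intensity.** The window is segmented into maximal monotone
runs delimited by strict direction reversals. For run $k$ with amplitude
$a_k = |x_{\text{end}} - x_{\text{start}}|$ and duration $d_k$ steps,

$$F = \frac{\sum_k a_k / d_k}{R\,(m-1)} \in [0, 1].$$

$F$ rewards both amplitude and frequency: a full-range alternation on
every step gives $F = 1$; a constant window gives $F = 0$; a single
monotone sweep through the whole range gives only $1/(m-1)^2$.

*Plateaus.* Runs of equal values extend the current monotone run, and a
run ends on the **last** extremal value before the reversal. This makes
$F$ continuous in the data (an infinitesimal perturbation of a plateau
cannot jump $F$) and keeps $F = 0$ for constant signals. The price is
that exact time-reversal symmetry of $F$ holds only for plateau-free
windows: a plateau at a turning point is assigned to the incoming run,
and reversing time swaps which run that is. No plateau convention gives
both continuity and exact reversal symmetry; we chose continuity, since
discretized Likert data are full of plateaus and a discontinuous measure
would be dominated by them.

**Distribution degree.** Sort the window ascending as $y_1 \le \dots \le
y_m$. Under perfectly even coverage of the range, any span of $c$ order
statistics would be $I_c = c R/(m-1)$ wide. Only under-dispersion is
penalised:

$$D = 1 - \frac{\sum_{c=1}^{m-1}\sum_{a=1}^{m-c} \max\{0,\; I_c - (y_{a+c} - y_a)\}}
               {\sum_{c=1}^{m-1} (m-c)\, I_c} \in [0, 1],$$

so $D = 1$ for an even full-range spread and $D = 0$ when all values
coincide. $D$ is permutation-invariant by construction. An
adjacent-spans-only variant ($c = 1$) is available via
`distribution_degree(spans = "adjacent")` for sensitivity analyses; the
all-spans version is the default and is what every closed-form example
in the test suite pins down.

**Composite.** $C = F \cdot D \in [0,1]$; $C = 0$ exactly when the window
is constant. $C$ is stamped on the window's **last** day (right
alignment), so a peak at day $t$ only uses information available by day
$t$ — the curve is usable prospectively, and "critical fluctuations
precede transitions" remains causally interpretable. Windows containing
missing values yield missing $C$; the per-day curve is the unweighted
mean over items (items are commensurable because $C$ is range-normalised
per item).

Both kernels are verified against independent brute-force
re-implementations to $10^{-12}$ on 1,000 random windows, and against
closed-form limits exactly.

## Transition detection and interval labelling

The global maximum of the item-averaged complexity curve is always a
transition; ties break to the earliest day (the earlier instability is
the theoretically meaningful event). Additional local maxima qualify as
secondary transitions when they reach `secondary_fraction` (default 0.9)
of the global peak and lie at least `min_separation` (default 14) days
from every already-accepted transition, considered in decreasing peak
order. The source study reports a second maximum for 2 of 9 patients but
no numeric criterion; both knobs are therefore exposed and recorded in
the run provenance.

A transition on day $t$ labels interval $k$ as OT when
$s_k < t \le s_{k+1}$ (half-open on the left); transitions before the
first or after the last scan snap to the nearest interval, mirroring
scans performed "shortly before or after" the transition point. Patient
intervals without a transition are NOT; every control interval is ISI.
Two transitions in one interval collapse to one OT with a warning.

## ROI changes and contrasts

Activation is summarised per subject × scan × ROI as significant-voxel
counts for the symptom-provocation > neutral contrast, over eight ROIs
(CC/SMA, DLPFC r/l, insula r/l, parietal r/l, cuneus). Two measures are
carried through:

* raw counts, and
* **weighted %**: counts normalised per patient to the single largest
  ROI × scan cell (not per-ROI maxima), scaled to 100. This gives
  high-count areas more statistical weight and offsets sensitivity
  differences between scanners, because the normaliser is within-subject.

Inter-scan change is the **absolute** difference $|\Delta|$ between the
bounding scans: the interval contrasts concern the *size* of
reorganisation while activation globally decreases over therapy, so
signed differences could not reproduce the contrast structure.

`contrast_report()` first averages within subject × label (each patient
contributes one OT and one NOT mean; each control one ISI mean), then
tests OT−NOT by paired $t$ (9 patients → df = 8) plus exact paired
Wilcoxon, and OT−ISI / NOT−ISI by Welch $t$ (fractional df) plus exact
rank-sum, all two-sided, with a point-biserial $r$ per contrast computed
on the pooled per-subject means under 0/1 coding (bands: small ≤ .20,
medium .21–.35, large > .35). No multiple-testing correction is applied
across ROIs by default (a Holm option exists), matching common practice
for small exploratory ROI panels.

The point-biserial values printed in the source study are not exactly
recoverable from its $t$ and df under any standard conversion; the
pooled-dummy-coding construction used here is therefore documented as
*the* definition, and its values should be compared qualitatively (band,
ordering) rather than digit-by-digit.

Inter-ROI structure is summarised by the mean and SD of the 28 pairwise
Pearson correlations across subjects at a chosen scan (so the paired
comparison of two correlation structures has df = 27). Correlations use
raw counts by default — the weighting was introduced for the change
analysis, not the correlation analysis — with `measure = "weighted"` as
an option.

## Statistical layer: numerical choices

* **Exact Wilcoxon with ties.** Daily Likert data and small voxel panels
  tie constantly, and the standard exact algorithms refuse ties. Both
  signed-rank and rank-sum nulls are therefore enumerated by dynamic
  programming on the doubled-rank lattice (average ranks are multiples of
  ½), which is exact for tied data too: exact for $n \le 25$ retained
  pairs (signed-rank) and $\min(n_1, n_2) \le 15$, $N \le 40$ (rank-sum);
  a tie-corrected normal approximation with continuity correction is used
  beyond. Zero differences are dropped (Wilcoxon's original rule) and
  logged. Two-sided p is $\min(1, 2\min(P_{\le}, P_{\ge}))$, which agrees
  with `wilcox.test`'s exact p in the tie-free case and with full
  enumeration everywhere it was checked.
* **Degenerate inputs.** Zero-variance paired differences give p = 1
  (all-zero) or a machine-floor p with a flag (constant non-zero);
  a Welch test with two zero-variance groups is an error; a constant
  bootstrap sample collapses the BCa interval to a point with a flag.
  `contrast_report()` converts such errors to `NA` columns so the mean
  differences are always reported.
* **Type-III ANOVA.** The group × transition-type interaction uses
  Type-III sums of squares under sum-to-zero contrasts (`car::Anova`),
  the convention that matches the original SPSS analysis and is stable
  under the unbalanced cell sizes that interval counts produce.
* **BCa bootstrap.** `boot::boot.ci(type = "bca")` with jackknife
  acceleration; default B = 10,000, seeded. Coverage is verified by
  simulation (95% ± 2% over 1,000 draws at n = 50).

## The synthetic cohort: what it emulates, and what it does not

Each patient-item is a latent AR(1) process ($\varphi = 0.6$) around a
baseline mean drawn from the middle half of the 1–7 scale, with
innovation SD $\sigma = 0.08R$. During the $w = 10$ days before the
injected transition day $\tau$ the innovation SD is multiplied by
$\kappa = 3$ (critical fluctuations *precede* the transition); from
$\tau$ onward the item mean shifts by $\pm 0.25R$ with an item-specific
sign (the new regime). Values are clipped to the scale and then rounded
to the Likert grid, in that order — a 7-point instrument truncates a
latent process before discretizing it. Observation lengths are drawn
uniformly from 37–65 days; scans sit at ~day 9, evenly spaced, the last
at $T-1$; each $\tau$ is placed inside its designated interval, with
single-transition patients drawing interval 1 with probability .75
(early transitions dominate in practice) and double-transition patients
drawing two distinct intervals at least 16 days apart where feasible.

The matched ROI panel draws scan-1 counts around per-ROI baselines
(spanning ~1,300–22,600 voxels; between-subject CV 0.3) with a common
within-subject latent factor giving inter-ROI correlation
$\rho_{\text{pre}} = 0.71$; each interval then moves every ROI by a
label-dependent magnitude (OT 7479, NOT 1904, ISI 697 voxels, noise SD
1,000) — decrementing when feasible, incrementing otherwise, so
$|\Delta|$ equals the drawn magnitude and counts stay non-negative.
Change noise after a subject's first transition uses
$\rho_{\text{post}} = 0.29$, eroding the initial correlation structure.

What the generator does **not** model: item content and subscale
structure, serial dependence beyond AR(1), weekend or therapy-schedule
periodicity, heavy-tailed or skewed rating distributions, scanner- or
session-level artefacts, and any biophysical BOLD mechanism. Passing
tests on this cohort therefore demonstrate that the *pipeline* recovers
what it injects — not that real therapy data behave this way.

## Known limitations

* **Day-level dating of transitions is biased early by construction.**
  The inflation window ($w = 10$) is longer than the complexity window
  ($m = 7$), so the windows ending on days $\tau-4 \dots \tau-1$ are all
  fully inflated and nearly exchangeable; the curve's global maximum is
  accordingly spread over the last ~5–6 pre-transition days. On 200
  synthetic patients the detected day falls within ±3 days of $\tau$
  about 67–77% of the time (never late), while the *interval* containing
  the transition — which is what the downstream contrasts consume — is
  recovered in ~98–99% of subjects. Correcting the day estimate would
  require knowledge of $w$, which a detector should not have; we report
  the peak day unadjusted and treat interval-level recovery as the
  operative criterion.
* Retrospective detection only: the package does not model the
  prospective scheduling of a fourth scan after an observed second
  maximum.
* No significance testing of individual complexity peaks (surrogate-data
  nulls would be the natural extension).
* The contrasts assume the ROI panel is given; ROI delineation,
  voxelwise thresholds and normalisation live upstream of this package.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run entirely from the seeded
generators: 1,000 random windows for kernel fidelity, 200 synthetic
patients for transition recovery, 5,000 null draws for paired-t
calibration, 1,000 draws (B = 1,999) for BCa coverage, and 100 cohort
replicates for the end-to-end ROI contrast — sizes chosen so the whole
suite completes in a few minutes on one CPU while keeping Monte-Carlo
error well inside the asserted margins.
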