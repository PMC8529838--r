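---
title: "Longitudinal plausibility scoring of EHR measurements: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal plausibility scoring of EHR measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Repeated vitals in EHR data (adult height in inches, weight in pounds)
contain entry errors — wrong units, transposed digits, records filed to the
wrong chart — at rates that matter for downstream use, e.g. BMI
classification. Atemporal checks (plausible ranges, population Z scores)
see each value in isolation; they flag stable but unusual patients and miss
errors whose values are population-typical. `ehrqa` scores each observation
against the subject's own history.

For one subject's series $y_1,\dots,y_n$ at times $t_1,\dots,t_n$ the index
value $y_i$ is compared with an exponentially weighted moving average
(EWMA) over the *entire* sequence, self included with weight 1 and
neighbors down-weighted as $e^{-|t_j-t_i|/\tau}$. The absolute deviation
$d_i = |y_i - \bar y_i|$ is standardized by
$\mathrm{SE}(d_i) = \sqrt{f_i\,\mathrm{Var}(y)}$ and converted to a
two-sided normal p-value $Q_R = 2(1-\Phi(d_i/\mathrm{SE}(d_i)))$. The
working assumptions are:

* measurements are independent draws around a locally stable subject-level
  truth, with common within-subject variance $\mathrm{Var}(y)$;
* the variable is (locally) stationary — the method suits height and
  weight, not quantities with fast physiological swings such as inpatient
  blood pressure;
* only time *intervals* matter; any origin (age, calendar years) gives
  identical scores, and units cancel out of $Z$.

The comparator score $Q_S = 2(1-\Phi(|y-\mu|/\sigma))$ uses a population
reference mean and SD and needs no history.

## The deviation-variance factor

Under independence, $\bar y_i - y_i$ is the linear combination
$\sum_j a_j y_j$ with $a_j = w_j/W - \mathbf 1[j=i]$, $W = \sum_j w_j$, so
its variance multiplier is

$$f_i = \sum_j a_j^2 = \frac{\sum_j w_j^2}{W^2} - \frac{2w_i}{W} + 1 .$$

A published sign convention writes $+2w_i/W$ for the middle term instead.
Both are implemented (`variance_variant = "derived"` / `"paper"`);
`derived` is the default because a Monte-Carlo experiment in the test suite
(20 random weight configurations, $10^5$ replicates each) shows the
simulated variance of $\bar y_i - y_i$ matching the derived factor within
three Monte-Carlo standard errors and excluding the alternative at the same
radius. The choice matters: the `paper` factor exceeds 1 (deflating $Z$ and
making the score conservative), while the derived factor is below 1 and —
with a correct $\mathrm{Var}(y)$ — yields exactly uniform null p-values,
which the calibration test verifies (flag rate at cutoff 0.05 within
binomial error of 5% over 1,000 clean 10-visit subjects).

## Tunable parameters

| parameter | units | default | rationale |
|---|---|---|---|
| `tau` (height) | years | 9.49 | heuristic $-(\xi/12)/\log\omega$ with 90% dependency at a 12-month gap: adult height is stable |
| `tau` (weight) | years | 0.5 | optimized value; the same heuristic at $\xi = 0.5$ months gives 0.4 |
| `var_y` (height) | in² | estimated | no published constant; estimated from the data by the one-way random-effects (ANOVA method-of-moments) within-subject component |
| `var_y` (weight) | lb² | 210 | optimized value; deliberately several times the true scale noise, which keeps the false-positive rate well below the nominal cutoff |
| `cutoff` | p-value | 0.05 | conventional; 0.01 is the usual stricter choice |
| `ref_mean`, `ref_sd` (height) | in | 69, 3 | fixed adult norms for the thresholding comparator |
| `ref_mean`, `ref_sd` (weight) | lb | 195, 40 | fixed adult norms |
| ranges | native | 40–100 in; 40–1000 lb | plausible-range eligibility filter, bounds inclusive |
| `min_age` | years | 17 | adult-only scoring (height stability assumption) |
| `max_same_day` | count | 3 | more than three same-day entries is treated as a computer entry error |
| subject cutoff | fraction | 0.20 | subject flagged when *strictly more than* 20% of scored records are flagged |

The within-subject variance is a *tuning constant*, not an unbiased noise
estimate: overstating it trades power for specificity. The ANOVA estimator
was chosen over a likelihood fit because it is closed-form and
deterministic — adequate for a constant — and on balanced data it agrees
with `lme4::lmer`'s REML component exactly (tested). The population
reference is shipped as fixed norms rather than re-estimated from the QA
target data, because estimating $\sigma$ from the very records under audit
inflates it with the errors being hunted; `ref_mean = NULL` restores
estimation from the input when a trusted reference extract is being used.

## Preprocessing rules

Range bounds are inclusive (boundary-valid data are kept). The age filter
keeps records at ages $\ge$ 17 (times must encode age for it to be
meaningful). Days with more than `max_same_day` measurements are removed
*entirely*: such bursts are most plausibly entry errors and no principled
survivor exists. Same-day grouping chains times equal within
`day_tolerance` (default half a day, 0.5/365.25 years) so day-precision
timestamps group correctly. Range and age criteria are disjoint, so their
order does not affect the kept set (tested as a property).

## Numerical and degenerate-input choices

* Ties in time are allowed; a same-timestamp neighbor gets weight
  $e^0 = 1$, identical to the self weight, with no special-casing.
* Within-series order is time, then `record_id` — deterministic under any
  input permutation (tested), which also fixes the same-day height chosen
  for BMI pairing (first by `record_id`).
* Single-measurement series cannot be scored; they are returned with
  missing scores, status `insufficient_history`, never flagged, and are
  excluded from both numerator and denominator of subject summaries.
* A zero reference SD is rejected (it would produce infinite $Z$); a zero
  within-subject variance estimate raises a degenerate-data warning.
* $Q_S$ uses $|Z|$ so below-mean values score symmetrically; without the
  absolute value, p-values above 1 would arise for them.
* Two-sided p-values are computed as `2 * pnorm(-|z|)`, numerically stable
  in the far tail.
* BMI uses the standard 703 lb/in² conversion; class boundaries are
  underweight $<$ 18.5, normal-to-overweight $[18.5, 30)$, obese I/II/III
  $[30, 40)$, obese III $\ge 40$, used as non-exclusive per-subject
  "ever in class" indicators (a 40.0 BMI is obese III).

## The synthetic-cohort generator

Real labeled EHR data cannot ship with a package, so the generator
(`cohort_spec()` / `generate_cohort()`) produces cohorts with the
statistical structure the method assumes, plus ground-truth error labels:

* per subject, a stable true height ($N(69, 3^2)$ in) and a baseline weight
  drawn from a two-component mixture — typical $N(185, 30^2)$ lb with a 15%
  obese subpopulation $N(285, 45^2)$. The mixture is deliberate: adult
  weight is right-skewed, and stable heavy subjects are exactly the
  patients an atemporal population threshold misjudges. A single Gaussian
  would make the population Z test well-calibrated and erase the contrast
  the method exists for;
* weight follows a Gaussian random walk (4 lb/√year) around its baseline;
* irregular visits from an exponential-gap renewal process, 2/year for
  height and 3/year for weight, over a follow-up of mean 12 (SD 5) years,
  with `time` encoding age (enrollment uniform between 25 and 75);
* observation noise 0.6 in / 6 lb — the scale of stadiometer/scale noise
  plus clothing and time-of-day variation. Setting the weight noise to
  $\sqrt{210}$ instead makes the default score exactly calibrated, which is
  how the calibration tests use the generator;
* 5% of records corrupted by default, equally across four mechanisms: unit
  confusion (×2.54 for height; ×2.2046 or ÷2.2046 for weight), digit slips
  (transpose/drop/insert on the integer part), gross outliers uniform over
  the plausible range, and wrong-patient values (another subject's
  concurrent value). Weight unit errors mostly stay inside 40–1000 lb, so
  the range filter cannot remove them (asserted in the tests) and the
  temporal-vs-atemporal contrast is genuinely exercised;
* per-subject random substreams derived from the seed, so a cohort is
  byte-reproducible and existing subjects are unchanged when `n_subjects`
  grows.

What the generator does *not* emulate: real demographics and their
height/weight correlations, informative visit timing (sicker patients visit
more), autocorrelated or drifting measurement error, missingness, and
errors that are themselves temporally structured (e.g. a mis-calibrated
scale for a month). Passing tests therefore demonstrate correct behavior
under the model's own assumptions plus realistic error mechanisms — not
performance on any particular health system's data.

## Evaluation harness and experiment sizes

`confusion_metrics()` treats flagged-as-error as positive and reports
FPR, power, PPV, NPV (undefined denominators as `NA`); `roc_sweep()`
sweeps the p-value cutoff (always including 0.01 and 0.05) and reports
trapezoidal AUC anchored at (0,0) and (1,1) — it matches `pROC`'s AUC to
machine precision when run over all observed cutoffs (tested).
`parameter_sweep()` grids over $\tau \times \mathrm{Var}(y)$ and selects
the maximum-power point subject to an FDR bound (FDR $= 1 -$ PPV, default
bound 0.2).

One selection caveat discovered during development and verified in the
tests: at the generating variance the score is calibrated, so its ~5% base
false-positive rate plus the contamination of the EWMA by neighboring
injected errors put a floor under the FDR; with a tight FDR bound the
selection is therefore structurally biased toward larger variances. The
variance-recovery test accordingly uses moderate (3.5–5σ) error shifts — so
power strictly decreases in the assumed variance — and a permissive bound
(0.5), under which the generating variance is identifiable and is indeed
selected.

Test problem sizes were chosen to keep the full suite fast while leaving
comfortable statistical margins: null calibration uses 1,000 subjects × 10
visits; the Monte-Carlo variance check 20 configurations × $10^5$
replicates; variance recovery 500 subjects × 10 visits (10% tolerance); the
head-to-head $Q_R$ vs $Q_S$ comparison a 200-subject default cohort at a
fixed seed, asserting the directional ordering (higher AUC, lower FPR,
higher power for $Q_R$) rather than any particular values, which would be
cohort-specific.

## Known limitations

* A single large error contaminates the EWMA of its neighbors (the average
  is not robust), costing specificity near errors; a robust center (e.g.
  weighted median) would trade simplicity and calibration for resistance.
* The independence assumption ignores genuine within-subject
  autocorrelation (weight trends); the random-walk component in the
  generator quantifies the effect only crudely.
* A sudden real change (weight loss after illness) is indistinguishable
  from an error by construction; flags are advisory, and `subject_qa`
  deliberately stops at reporting proportions rather than deleting data.
* Scores require $n \ge 2$; cohorts with many single-visit subjects get no
  longitudinal protection for them.
* The thresholding comparator inherits whatever bias its reference carries;
  with in-sample estimation its SD absorbs the very errors under test.
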