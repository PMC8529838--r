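# ehrqa — longitudinal plausibility scoring for EHR measurements

Electronic health record (EHR) vitals such as height and weight are entered
by hand, at scale, and without research-grade monitoring. Before they can
support real-world-evidence analyses they need quality assessment, and the
standard tool — a fixed plausible range or a population Z threshold — judges
each value *in isolation*. That atemporal view fails in both directions: a
consistently 380-lb patient has every record flagged even though the data
are internally coherent, while a 120-lb entry for an 80-lb patient sails
through because 120 lb is an unremarkable number.

`ehrqa` implements a score-based, *temporal* alternative for repeated
continuous measurements, aimed at biostatisticians and data engineers
curating longitudinal EHR extracts. Each observation is judged against the
patient's own history and receives a continuous plausibility score, so
downstream users choose their own strictness instead of inheriting a binary
rule.

## The scores

For a subject's measurements $y_1,\dots,y_n$ at times $t_1,\dots,t_n$
(decimal years), the index observation $y_i$ is compared with an
exponentially weighted moving average over the entire sequence,

$$\bar y_{i} = \frac{\sum_j w_j y_j}{\sum_j w_j},\qquad
  w_j = \begin{cases} 1 & j = i\\ e^{-|t_j - t_i|/\tau} & j \ne i,\end{cases}$$

so near-in-time neighbors dominate and the decay scale $\tau$ (years) sets
how fast influence fades. With $d_i = |y_i - \bar y_i|$ and an assumed
within-subject variance $\mathrm{Var}(y)$, independence gives
$\mathrm{Var}(d_i) = \left(\frac{\sum_j w_j^2}{W^2} - \frac{2w_i}{W} + 1\right)
\mathrm{Var}(y)$ with $W = \sum_j w_j$ (the sum of squared coefficients of
the linear combination $\bar y_i - y_i$; an alternative published sign
convention for the middle term is available as
`variance_variant = "paper"`). The longitudinal score is the two-sided
normal p-value

$$Z_{R,i} = d_i / \mathrm{SE}(d_i), \qquad Q_{R,i} = 2(1 - \Phi(Z_{R,i})),$$

flagged when $Q_R \le$ a chosen cutoff (0.05 by default). The atemporal
comparator scores each value against a population reference:
$Z_S = (y - \mu)/\sigma$, $Q_S = 2(1-\Phi(|Z_S|))$.

A heuristic sets $\tau$: to place dependency $\omega$ on neighbors $\xi$
months away, $\tau = -(\xi/12)/\log\omega$. For stable adult height,
$\omega = 0.9$ at $\xi = 12$ gives $\tau = 9.49$ (neighbors 2 and 5 years
away then keep 81% and 59% weight); the shipped weight default is the
optimized $\tau = 0.5$ with $\mathrm{Var}(y) = 210\,\mathrm{lb}^2$.

Both scores are unit- and time-origin-invariant; at least two measurements
are required for $Q_R$, and single-measurement subjects are reported
unscored rather than flagged.

## Worked example

A small labeled synthetic cohort ships with the package:

```r
library(ehrqa)
rec    <- read_records(system.file("extdata", "example_records.csv",
                                   package = "ehrqa"))
pre    <- preprocess_records(rec)          # range / age / same-day filters
scored <- score_records(pre$kept)          # adds Q_R and Q_S columns
head(scored[order(scored$q_r), c("subject_id", "variable", "time", "value",
                                 "ewma", "z_r", "q_r", "q_s")], 5)
```

```
    subject_id variable  time  value   ewma    z_r        q_r       q_s
186     S00001   weight 53.06 848.00 438.90 37.485 1.646e-307 6.567e-60
227     S00002   weight 72.17 526.94 307.36 20.911  4.227e-97 1.054e-16
226     S00002   weight 72.02 149.86 263.84 10.288  7.975e-25 2.591e-01
264     S00003   weight 75.97 307.07 199.24  9.252  2.193e-20 5.082e-03
154     S00006   height 68.97  45.22  61.89  8.957  3.336e-19 2.230e-15
```

Row 226 is the method's point in one line: 149.86 lb is a perfectly
ordinary weight ($Q_S = 0.26$, invisible to thresholding) but wildly
inconsistent with this subject's own ~260-lb history
($Q_R \approx 10^{-24}$) — a kilograms-entered-as-pounds error. Evaluating
the flags against the generator's ground-truth labels:

```r
lab <- read.csv(system.file("extdata", "example_labels.csv", package = "ehrqa"))
lab$is_error <- as.logical(lab$is_error)
ok <- !is.na(scored$q_r)
confusion_metrics(scored$flag_r[ok], lab, scored$record_id[ok])
#> confusion: tp=13 fp=12 tn=350 fn=2
#>   FPR=0.0331 power=0.8667 PPV=0.5200 NPV=0.9943
```

Subject-level QA (`summarize_subjects(scored, 0.20)`) reports, per subject,
the proportion of flagged records and whether it exceeds 20%; the BMI use
case (`bmi_table`) pairs same-day height/weight records, computes
$703\,w/h^2$, and compares "ever in BMI class" proportions with no QA,
thresholding QA and longitudinal QA.

Everything is also available from a shell via the thin wrapper in
`inst/cli/ehr-qa.R`:

```sh
Rscript inst/cli/ehr-qa.R simulate --out records.csv --labels labels.csv \
    --n-subjects 200 --seed 1
Rscript inst/cli/ehr-qa.R score --input records.csv --output scored.csv
Rscript inst/cli/ehr-qa.R evaluate --records records.csv --labels labels.csv \
    --out metrics.csv
```

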