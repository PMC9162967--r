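---
title: "Desaturation burdens and postoperative renal impairment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Desaturation burdens and postoperative renal impairment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxiburden)
```

## The problem

During coronary artery bypass grafting (CABG), episodes of tissue
hypoperfusion and hypoxia are suspected contributors to postoperative
renal impairment. Near-infrared spectroscopy (NIRS) sensors placed over
the renal regions (flank), the forehead (cerebral) and the thenar muscle
(peripheral) give continuous, non-invasive tissue oxygen saturation
readings in percent. `oxiburden` condenses each intraoperative saturation
trace into *desaturation burdens* — time-integrated deficits below
clinically meaningful thresholds — and evaluates each burden as a
predictor of a sensitive, creatinine-based definition of postoperative
renal impairment.

Because multi-channel intraoperative oximetry with linked outcomes is not
publicly deposited, the package ships a synthetic-cohort generator with a
*known* generative link between desaturation and outcome, so the entire
pipeline can be exercised and validated end to end against designed
values.

## Data model

A trace is a strictly increasing sequence of timestamps (decimal minutes
from induction of anaesthesia) with saturations in $[0, 100]$%, plus two
event markers: surgical incision and end of surgery. Missing samples are
represented as gaps in the time grid, never as sentinel values. A patient
record bundles up to five channels (`renal_left`, `renal_right`,
`renal_mean`, `cerebral`, `peripheral`), a creatinine series (preoperative
baseline plus postoperative days 1–7, µmol·l⁻¹) and covariates.

Cohorts are stored as one long-format CSV per patient (`time_min,
channel, value`) plus a cohort-level CSV of events, creatinine and
covariates. Readers validate every record and return violators in a
rejected list with reasons rather than dropping them. A record is
excluded from analysis when it has no renal channel, no peripheral
channel, or when those traces do not cover the intraoperative window —
mirroring the bookkeeping a real secondary analysis has to do.

## Baselines and burdens

**Baseline.** The individual baseline of a channel is the arithmetic mean
of all samples in the 5 minutes immediately preceding incision
(configurable window). Post-induction baselines are used because
deviations below a stable anaesthetised level are the physiologically
relevant exposure during surgery.

**Bilateral averaging.** When both renal sides were recorded, the merged
`renal_mean` trace averages left and right at common time points and
passes single-sided samples through; the Spearman correlation of the
paired samples is reported alongside. Records with a single renal side
use that side directly.

**Absolute-threshold burden.** For a threshold $T$ (conventionally 90,
80, 70, 60%):
$$\mathrm{AUT}_{<T} = \int_{t_\text{inc}}^{t_\text{end}}
  \max\{T - S(t),\, 0\}\, dt \qquad [\%\cdot\min]$$

**Relative-threshold burden.** For a fraction $f$ below the individual
baseline $B$ (conventionally 5, 10, 15%):
$$\mathrm{AUT}_{>f} = \int_{t_\text{inc}}^{t_\text{end}}
  \max\{(1-f)B - S(t),\, 0\}\, dt$$
For the peripheral channel only the 10%-below-baseline burden is
computed, matching the single peripheral exposure the panel is designed
around.

**Renal-specific differential burden.** Both the renal and peripheral
series are renormalised so their baselines equal 100%; with
$d(t) = S^{\text{per}}_{\text{norm}}(t) - S^{\text{ren}}_{\text{norm}}(t)$,
the burden is $\int \max\{d(t), 0\}\,dt$. Only epochs in which the renal
region desaturates *proportionally more* than the periphery accrue
burden; negative excursions are clipped, never subtracted. The
differential is evaluated on the union of the two channels' sample grids
(each channel linearly interpolated), since the channels generally come
from different monitors with unaligned clocks.

### Numerical choices

* **Integration rule.** The deficit-times-time formulation of the burden
  implies rectangle integration per sample interval. The default is a
  clipped *trapezoidal* rule on the piecewise-linear interpolant with
  exact threshold-crossing handling inside an interval: it is exact for
  the linear-interpolation signal model and converges to the same value
  as sampling density grows. `method = "rectangle"` (left-sample hold)
  preserves the literal reading and is kept testable; for a constant
  deficit the two rules agree exactly.
* **Gaps.** Sample intervals longer than the gap tolerance (default
  2 min) contribute zero burden — a conservative choice, since no
  imputation policy can be defended without knowing why the data are
  missing — and the total within-window gap time is reported with every
  burden.
* **Analysis window.** Burdens accrue over
  $[t_\text{incision}, t_\text{end}]$: the baseline window ends at
  incision, so burden accrual starts there. Both endpoints are
  configurable, because export conventions differ on whether recording
  stops at the end of surgery.
* **Clipping.** Contributions above threshold count as zero, never
  negative; a burden is always $\ge 0$ and is exactly 0 for a trace that
  never crosses its threshold.

## Outcome definition

Postoperative renal impairment is a serum creatinine rise strictly
greater than 10% above the individual preoperative baseline on any of
postoperative days 1–7. The boundary is strict — an exact +10% rise is
negative — and is evaluated as `value > baseline * 1.10` on the raw
concentrations so floating-point rounding of the ratio can never flip the
boundary case. Day-of-surgery values are excluded from the window;
"postoperatively" is read as days 1–7, both configurable. This definition
is deliberately more sensitive than KDIGO/AKIN/RIFLE staging, which the
package does not implement.

## Statistical suite

* **Group comparisons.** Continuous variables are routed by per-group
  Shapiro–Wilk tests at $\alpha = 0.05$: both groups normal ⇒ Student's
  independent t test with mean (SD) summaries, otherwise Mann–Whitney U
  with median [IQR]. Categorical variables use Fisher's exact test when
  any expected cell count is below 5, else the Pearson chi-square test.
  A group whose values are all identical is routed nonparametrically
  (the Shapiro–Wilk statistic is undefined there).
* **Correlation** is Spearman's rank correlation throughout.
* **ROC analysis.** The AUROC is computed from midranks (the
  Mann–Whitney construction, ties counted ½) and therefore equals the
  exhaustive positive-negative pair-count statistic exactly. The 95% CI
  uses the Hanley–McNeil asymptotic standard error with normal
  quantiles, clipped to $[0,1]$; this matches the default nonparametric
  output family of mainstream clinical statistics software. The p value
  is the two-sided normal test of AUROC = 0.5 with that SE. The
  operating cutoff maximises Youden's $J$ over midpoints between
  consecutive unique predictor values, ties broken toward higher
  specificity; subjects classify positive when the oriented predictor
  strictly exceeds the cutoff. Constant predictors are retained in
  tables with AUROC 0.5 and a `degenerate` flag.
* **Multiplicity.** No multiple-testing correction is applied; the
  report instead records the number of tests performed so readers can
  judge the familywise behaviour themselves.

## The synthetic cohort generator

The generator emulates the statistical regime the analysis assumes; it
is not a haemodynamic or pharmacokinetic model.

* **Traces.** Each channel is a baseline plateau (per-channel Gaussian
  baselines, defaults: renal 79.5 (9.5)%, cerebral 64 (10)%, peripheral
  84 (7)%) plus stationary AR(1) noise (SD 2%, lag-1 persistence 0.9 at
  the 0.5-min sampling default) and Poisson-arriving desaturation
  episodes during surgery. Episodes are half-cosine excursions (smooth
  onset and offset) with gamma depths and log-normal durations — a shape
  chosen deliberately because its per-episode area has a closed form,
  which the oracle tests exploit. Surgery duration is log-normal
  (median 180 min, log-SD 0.155); incision is 20 min after induction.
* **Bilateral renal structure.** Left and right share their episode
  process and 60% of their noise variance, and differ by small baseline
  offsets; with the default noise and episode mix this yields a
  within-patient left–right Spearman correlation near 0.80. About 15% of
  patients are generated with a single renal side.
* **Outcome link.** Impairment labels are Bernoulli draws from a
  logistic link on `log1p` of the patient's *realised* peripheral
  relative-10% burden — computed with the package's own burden machinery,
  so the designed predictive strength is exactly what the pipeline can
  recover. The slope default (0.75) was fixed once, by simulation, to
  give a designed AUROC near 0.77 at 27% prevalence; the intercept is
  solved per cohort so the mean impairment probability equals the
  specified prevalence. `designed_auroc()` recomputes the implied AUROC
  for any spec by large-sample simulation (default 2 000 patients).
  There is no direct renal→outcome link: the renal burdens are null
  predictors by construction. (Surgery duration drives episode
  opportunity on all channels, so renal burdens retain a small marginal
  association with outcome through the peripheral pathway — as they
  would in real data.)
* **Creatinine.** Baselines are log-normal (median 84 µmol·l⁻¹). Each
  patient's postoperative trajectory is a positive peak-and-decay shape
  scaled so its maximum relative rise *exactly* equals a target drawn
  from U(0.12, 0.40) for impaired and U(−0.06, 0.095) for non-impaired
  patients; the labelling rule applied to the generated series therefore
  reproduces the drawn label for every patient. Concentrations are kept
  at full precision (not rounded to integer µmol·l⁻¹) to preserve that
  exactness.
* **On-pump arm.** On-pump patients additionally receive a slow
  renal-only half-cosine desaturation drift (default 9% by end of
  surgery), producing a stochastically larger renal-specific
  differential burden on pump with no effect on the outcome link.
* **Calibration.** The episode-process defaults were frozen after a
  one-off calibration run so that the burden distributions land in a
  plausible clinical range (renal absolute-90 burdens of a few thousand
  %·min, peripheral relative-10 burdens with a spike at zero and a heavy
  right tail). They are calibration aids for realism, not claims about
  any particular cohort.

**What passing tests do and do not show.** The generator produces
piecewise-smooth signals with known episode areas, exact label
consistency and a known outcome link. Real NIRS data additionally
contain sensor artefacts, step changes from probe repositioning,
device-specific quantisation and autocorrelation structure, and
informative missingness — none of which are modelled beyond the gap
policy. Validation on synthetic cohorts therefore demonstrates the
correctness of the *computations* and the calibration of the
*statistics*, not clinical performance on any real population.

## Validation design and problem sizes

The test suite checks, among others:

* agreement of both burden rules with a dense (0.001-min) rectangle-rule
  oracle on 100 random piecewise-linear traces, to 0.1 %·min;
* per-episode closed forms for scripted dips, and exact clipping of the
  renal-specific differential;
* exact equality of the AUROC with the brute-force pair-count statistic
  on 200 random labelled sets (n ≤ 50), plus label-flip antisymmetry and
  invariance under strictly increasing transforms, and a cross-check
  against an independent ROC implementation;
* the strict creatinine boundary, window exclusion and scaling
  invariance;
* designed-value recovery on 200 replicate cohorts of n = 41 at 27%
  prevalence (mean recovered peripheral AUROC within ±0.05 of the
  designed value; renal-burden 95% CIs covering 0.5 in ≥ 90% of
  replicates);
* uniformity of routed-comparison p values over 1 000 null datasets
  (Kolmogorov–Smirnov at α = 0.01);
* byte-identical cohort files and report JSON for a fixed seed and
  config.

These sizes keep the full suite comfortably within a coffee break on a
single core while leaving the Monte-Carlo error of each check well below
its tolerance.

## Known limitations

* The gap policy (zero burden inside long gaps) biases burdens downward
  for patients with poor signal coverage; the reported per-burden
  `gap_min` lets analysts filter such patients.
* The Hanley–McNeil interval is asymptotic and can be anticonservative
  at very small class counts; a bootstrap or DeLong interval would be a
  natural extension.
* The baseline is a single pre-incision window mean; no drift or
  artefact correction is applied to it.
* Whether the single preoperative creatinine or an average of several
  should anchor the relative rise is left to the data provider; the type
  carries one baseline value.
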