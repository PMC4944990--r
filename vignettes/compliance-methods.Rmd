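---
title: "Measuring social psychophysiological compliance from dyadic heart-rate variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring social psychophysiological compliance from dyadic heart-rate variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsync)
```

## The problem

When two people collaborate intensely — here, pairs of novice programmers
sharing one workstation in a classroom — their physiological signals tend
to become correlated. This *social psychophysiological compliance* (SPC)
is of interest as an objective, unobtrusive index of collaboration
quality. The catch in a field setting is that everyone in the room shares
the same environment: instructor announcements, the session clock, general
fatigue. A naive correlation between two people's heart signals mixes
dyad-specific coupling with these classroom-wide confounders.

`dyadsync` implements a pipeline that separates the two: within-dyad
correlations of windowed heart-rate-variability (HRV) features are
compared against a permutation null built from *re-paired* participants
who sat in the same class. Whatever correlation survives the re-pairing is
environmental; whatever exceeds it is attributable to the pairing itself.

## From ECG to features

1. **R-peak detection** (`detect_r_peaks()`): a band-pass (5–15 Hz) /
   differentiate / square / integrate detector with an adaptive
   signal/noise threshold and a 250 ms refractory period; peak times are
   refined to the raw-signal maximum within ±40 ms. The detector family
   is deliberately simple and dependency-light; the function is a plug-in
   seam — any vector of beat times can enter the pipeline directly
   (`beats_to_nn()`).
2. **Interbeat intervals** (`peaks_to_ibi()`): successive peak-to-peak
   delays in ms, each timestamped at its terminating beat.
3. **Artifact filtering** (`filter_abnormal()`): intervals outside
   [300, 2000] ms, or deviating more than 30% from the running median of
   the previous (up to 10) accepted intervals, are *dropped* — never
   interpolated — mirroring the normal-to-normal (NN) convention that
   abnormal beats are not counted. The deviation rule engages after 5
   accepted intervals. All thresholds are arguments: artifact criteria in
   field recordings are a judgment call, so they must be auditable and
   changeable. A rejection breaks temporal adjacency, which the rMSSD
   computation respects. Filtering is idempotent.
4. **Windowed features** (`feature_matrix()`): over sliding windows of
   length $L$ = 60–300 s with overlap $L/3$ (step $2L/3$), three
   time-domain features per participant $i$ and window $t$:
   * $x_i^{HR}(t) = 60000 / \overline{NN}$ (bpm),
   * $x_i^{SDNN}(t)$ = sample SD of the NN intervals (ms),
   * $x_i^{rMSSD}(t)$ = root mean square of successive NN differences
     (ms), adjacent pairs only.

   Time-domain features are used because they remain reliable down to
   60 s windows, unlike short-window spectral HRV. A window is *valid*
   when it contains at least `min_beats` (default 10) intervals; validity
   is shared across the three features so dyad comparisons use a common
   support, and invalid windows are flagged rather than dropped.

The overlap convention deserves a note: "overlap of one third of the
window length" is read literally as overlap $= L/3$, so consecutive
windows advance by $2L/3$. The alternative reading (step $= L/3$) is
defensible, so the overlap is a `window_spec()` argument rather than a
constant.

Whether the pre-task baseline period should be excluded from the
correlated span is equally ambiguous; the analysis origin defaults to the
recording start (baseline included) and is configurable via
`window_spec(origin_s = )`.

`rmssd_feature()` computes the *root* mean square. Informal usage
sometimes says "mean square of successive differences"; the root form is
the canonical definition and is used throughout.

## The compliance statistic and its null

For a feature $F$ and window length $L$, each collaborating dyad $(i, j)$
contributes a Pearson correlation $r_d = \mathrm{cor}(x_i^F, x_j^F)$ over
jointly valid windows (pairwise deletion; a dyad needs at least 3 joint
windows and non-constant vectors, otherwise it is excluded with a
warning and counted). The classroom statistic is the arithmetic mean

$$\mu_{true} = \tfrac{1}{n}\sum_d r_d .$$

The null keeps every first member fixed and re-pairs it with a second
member drawn uniformly at random *within the same class* — preserving
both the shared environment and the first/second role structure — giving
draws $\mu_r$ (`sample_pairing()`, `null_distribution()`; default 10000
draws). The true pairing stays in the permutation support, as uniform
sampling implies. From the draws:

* the 2.5th/97.5th percentiles (linear-interpolation definition, i.e.
  `quantile(type = 7)`, fixed for bit-reproducibility) give the null 95%
  CI;
* the two-tailed p-value uses add-one smoothing,
  $p = \min\!\big(1,\, 2\min\big(\tfrac{1 + \#\{\mu_r \ge \mu_{true}\}}{N+1},
  \tfrac{1 + \#\{\mu_r \le \mu_{true}\}}{N+1}\big)\big)$, standard
  practice to avoid reporting $p = 0$ from finite Monte Carlo;
* p-values are Holm–Bonferroni adjusted (`holm_bonferroni()`, a
  validating wrapper over `stats::p.adjust`). The default family is the
  three features within one window length, matching how results are
  conventionally tabulated per window; the family is configurable
  (`spc_test(adjust = FALSE)` plus a manual adjustment) because the
  choice — per window, or all features × windows jointly — is genuinely
  open and the data cannot settle it.

`spc_test()` packages statistic, CI, and p-values per feature;
`spc_study()` runs the full grid (seven window lengths, three features)
plus the regression below.

## Compliance and self-reported workload

Participants rate six 0–10 items after the session: mental demand (MD),
temporal demand (TD), performance (Pe), effort (Ef), frustration (Fr)
and concentration while navigating (Na); the physical-demand item of the
standard task-load instrument is excluded as irrelevant to seated
programming. Per dyad, member scores are summed (`dyad_sums()`, range
0–20) and the per-dyad correlation is regressed on them:

$$r_d \sim \beta_0 + \beta_m MD_d + \beta_t TD_d + \beta_p Pe_d +
  \beta_e Ef_d + \beta_f Fr_d + \beta_n Na_d .$$

`spc_lm()` fits this by ordinary least squares (via `stats::lm`) and
reports estimates, standard errors, t-based 95% CIs with $n - 7$ degrees
of freedom — the default of standard linear-model summaries, and the
construction that reproduces published interval widths of roughly
estimate ± 2.18·SE at $n = 19$ — and adjusted $R^2$.

Reference values for all of this ship with the package:
`study_dyads()` returns the per-dyad table of a published classroom
field study (19 dyads), from which the compliance means, the regression
and the instrument means can be recomputed directly — see the README's
worked example.

## The synthetic classroom generator

Real classroom ECG is bulky and personal; the generator
(`simulate_classroom()`) produces classrooms with the statistical
structure the analysis assumes, with known ground truth, so every stage
is testable. Per participant, interbeat intervals are

$$IBI_k = m(t_k) + w\,W(t_k) + \sigma(t_k)\,\varepsilon_k ,$$

* $m(t)$: base interval (800 ms, i.e. 75 bpm) or, for a *trending*
  participant, the interval tracking a heart rate that drifts by
  `hr_trend_slope_bpm_per_min` (default −0.05 bpm/min — gradual
  relaxation over a ~90-minute session). Trend flags are assigned to a
  fraction `trend_participation` (default 0.8) of participants,
  independently of the pairing: the drift emulates a classroom-wide
  process, so it must raise *all* pair correlations of HR, paired or
  re-paired, equally. Because non-trending participants' fitted HR
  slopes are sign-random noise, the expected fraction of dyads whose
  both members show a negative fitted trend is roughly
  $(0.8 + 0.2/2)^2 \approx 0.81$.
* $W(t)$: a private, slow mean-level wander (OU process, SD
  `mean_wander_ms` = 10 ms) keeping HR correlations below 1.
* $\sigma(t) = \texttt{noise\_sd\_ms}\cdot
  \exp(g L(t) - g^2/2)$: beat-noise dispersion modulated by a slow
  latent $L$, with gain $g = 0.5$. $L$ is a unit-variance
  exponentially-smoothed Gaussian (discretised OU) process with
  timescale `sdnn_latent_timescale_s` = 120 s — the simplest stationary
  process with controllable window-scale autocorrelation. For dyad
  members, $L = \sqrt{\kappa}\,S + \sqrt{1-\kappa}\,P$ with a shared
  path $S$ and private paths $P$, so the dispersion latents of a dyad
  correlate exactly $\kappa$.

Coupling enters through the *dispersion* only, never the mean interval.
This reproduces the dissociation the analysis is designed to detect:
windowed SDNN (and rMSSD) track $\sigma(t)$, so their compliance is
pairing-specific and grows with $\kappa$, while HR tracks $m(t) + W(t)$,
whose correlation is driven by the shared drift regardless of pairing.

Defaults are chosen once as the study conditions: 19 dyads in classes of
5/5/5/4 (38 participants), 5400 s sessions, per-dyad $\kappa$ evenly
spaced 0.1–0.9 (collaboration quality plausibly varies across a
classroom, and without variation a compliance-on-workload regression
would have nothing to recover), beat noise 15 ms. Self-report items are
Gaussians rounded and clipped to 0–10 with means/SDs typical of the
instrument (MD 6.0/2.05, TD 6.0/1.88, Pe 6.4/2.50, Ef 6.3/2.62, Fr
4.2/2.91, Na 8.1/1.69); the expected *dyad sum* of temporal demand
decreases in $\kappa$ with slope `tlx_temporal_effect` (default −6,
giving an expected compliance-on-TD-sum gradient of about −0.14 per
point, the scale reported in field data). All randomness flows from a
single stream seeded by `config$seed`, so identical configs are
bitwise-reproducible.

Beat times are cumulative interval sums; because the slow latents are
evaluated at beat times that themselves depend on the intervals, the
generator runs two fixed-point passes (the latents vary on 120 s scales,
so the remaining timing error is negligible). Intervals are clamped to
(300, 2000) ms to guarantee the physiological invariant.

`synthesize_ecg()` can render beats into a QRS-like waveform (Gaussian
template over noise) to exercise the peak detector; it makes no claim to
realistic PQRST morphology, respiration, or electrodermal activity.

### What the generator does and does not emulate

It reproduces: dyad-coupled slow variability driving SDNN compliance; a
classroom-wide HR drift driving pairing-independent HR correlation; a
negative workload–compliance association; the instrument's marginal
distributions. It does not model: ectopic beats or realistic artifact
morphology (the artifact filter is exercised with injected outliers
instead), respiratory sinus arrhythmia, dyad acquaintance history, or
any EDA channel. Passing tests therefore validate the *pipeline's
statistical behaviour* under the assumed structure, not the detector's
performance on messy field ECG.

## Numerical and testing choices

* **Exchangeable-null calibration** uses $\kappa = 0$: with any common
  $\kappa > 0$ each dyad shares its own latent, so true pairs are
  special and the pairing is not exchangeable. At $\kappa = 0$ the
  permutation p-value is uniform (verified by rank-uniformity
  simulation), and the type-I test asserts the rejection rate at
  $\alpha = 0.05$ within binomial bounds over 200 replicate classrooms
  at 500 permutations per test — the permutation count is scaled down
  from the 10000 used for reporting, which changes only Monte-Carlo
  resolution, not calibration.
* **Power** is checked at $\kappa = 0.8$ (25 replicates, 500
  permutations): rejection in over 80% of classrooms; under the default
  conditions the measured power is essentially 1.
* **Sign recovery** of the workload effect is asserted at a configured
  effect of −10 over 30 full-pipeline replicates. At the default −6 the
  recovery rate is about 94% — real but close enough to 90% that a small
  replicate count would make a threshold test a coin flip; the stronger
  setting tests the same qualitative invariant (negative configured
  effect ⇒ negative recovered slope) on a budget.
* Replicate-heavy tests use smaller classrooms (2 classes × 3 dyads) and
  shorter sessions (1800–3600 s) where the property under test does not
  depend on the full scale; single-run integration tests use the full
  default classroom.
* Degenerate inputs: flat ECG yields no peaks (or an error, by choice);
  windows with too few beats are invalid flags, not exceptions; constant
  feature vectors make a dyad's correlation undefined — the dyad is
  excluded with a warning and counted, never imputed.
* The artifact filter's sequential running-median rule is implemented in
  C++ (beat series run to ~7000 intervals per participant and the rule
  is inherently order-dependent); a plain-R sequential oracle pins its
  behaviour in the tests.

## Limitations

The permutation null conditions on the realised feature vectors, so it
tests exchangeability of the pairing, not model fit. With 19 dyads the
workload regression (7 parameters) is near its sensible minimum and the
printed adjusted $R^2$ values carry wide sampling error. The Holm family
ambiguity above changes adjusted p-values by small factors. And all
validation rests on the generator's structure; field recordings bring
artifact regimes the synthetic substrate only caricatures.
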