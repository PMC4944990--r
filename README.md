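# dyadsync

Quantifying **social psychophysiological compliance (SPC)** — the
correlation that develops between the physiological signals of two
people collaborating intensely — from dyadic single-channel ECG, with a
permutation test that separates dyad-specific coupling from
classroom-wide confounders.

The motivating setting is a field study of pair-programming: pairs of
students ("dyads") work at one workstation in a shared classroom while
wearing lightweight ECG sensors, and afterwards rate their task load
(NASA-TLX items plus a navigating-concentration item). Everyone in the
room shares the session clock, announcements, and growing fatigue, so a
naive correlation between two participants' heart signals conflates
shared environment with genuine interpersonal coupling. `dyadsync`
addresses this with a class-restricted permutation null.

## The method

For each participant *i*, ECG is reduced to an artifact-filtered
normal-to-normal (NN) interbeat-interval series, and three time-domain
HRV features are computed in sliding windows of length *L* (60–300 s,
overlap *L*/3):

- **HR** = 60000 / mean(NN) in bpm — an index of general activation;
- **SDNN** = sample SD of the NN intervals (ms);
- **rMSSD** = root mean square of successive NN differences (ms).

For every collaborating dyad (*i*, *j*) the feature vectors are
correlated, r_d = cor(x_i, x_j) (Pearson, jointly valid windows), and
the compliance statistic is their classroom mean

> μ_true = mean(r_1, …, r_n).

The null hypothesis — pairing doesn't matter, only the shared room does —
is simulated by re-pairing each first member with a second member drawn
uniformly at random *within the same class* (10000 draws of μ_r by
default). The empirical 2.5/97.5 percentiles give the null 95% CI; a
two-tailed add-one-smoothed p-value is computed per feature and
Holm–Bonferroni-adjusted across the features of each window length.
Finally, per-dyad compliance is regressed on the dyads' summed
self-report items:

> r_d ~ β0 + βm·MD + βt·TD + βp·Pe + βe·Ef + βf·Fr + βn·Na

with t-based 95% CIs (df = n − 7) and adjusted R².

A synthetic classroom generator (`simulate_classroom()`) produces beat
series with dyad-coupled slow variability (driving SDNN compliance), a
classroom-wide HR drift (driving pairing-independent HR correlation),
and workload reports tied to the coupling — the ground truth used by the
test suite. See the methods vignette
(`vignettes/compliance-methods.Rmd`) for the model and all numerical
choices.

## Worked example

The per-dyad table of a published 19-dyad classroom field study ships
with the package, so the headline numbers can be recomputed in seconds:

```r
library(dyadsync)
d <- study_dyads()

mean_dyad_correlation(d$SDNN_300)$mu
#> [1] 0.29

spc_lm(d, d$rMSSD_300)
#> Compliance ~ summed self-reports (OLS, 19 dyads)
#>   adjusted R-squared: 0.503
#>         term estimate std_error  ci_lo  ci_hi p_value
#>  (Intercept)    2.464     0.696  0.947  3.981   0.004
#>           MD   -0.015     0.033 -0.086  0.057   0.666
#>           TD   -0.148     0.035 -0.224 -0.071   0.001
#>           ...
```

The mean within-dyad SDNN correlation at 300 s windows is 0.29, and the
rMSSD-compliance regression explains half the between-dyad variance
(adjusted R² 0.50), with temporal demand the only significant item: one
extra point of summed temporal demand predicts 0.15 *less* compliance
(95% CI −0.22 to −0.07) — dyads that felt less time pressure were more
physiologically synchronized.

End to end on synthetic data:

```r
cls <- simulate_classroom(classroom_config(seed = 42))
st  <- spc_study(cls, window_lengths_s = c(60, 300),
                 n_permutations = 2000, seed = 42)
st
#> Compliance study: 19 dyads, windows 60/300 s, 2000 permutations
#>   window_length_s feature mu_true   ci_lo ci_hi p_raw n_dyads p_adjusted
#> 1              60      HR   0.413  0.3400 0.433 0.385      19      0.385
#> 2              60    SDNN   0.474 -0.0326 0.239 0.001      19      0.003
#> 3              60   rMSSD   0.467 -0.0342 0.223 0.001      19      0.003
#> 4             300      HR   0.475  0.3919 0.493 0.323      19      0.323
#> 5             300    SDNN   0.490 -0.0363 0.254 0.001      19      0.003
#> ...
```

This reproduces the signature dissociation: HR correlations are high for
*any* same-class pair (μ_true inside the null CI — the shared drift, not
collaboration), while SDNN/rMSSD compliance far exceeds its null
(adjusted p ≈ 0.003) because only true dyads share the slow variability
latent.

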