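---
title: "Detecting collective disorientation in opinion-polarity time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting collective disorientation in opinion-polarity time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarwatch)
```

## The problem

Public-health surveillance increasingly watches social media for shifts in
vaccine sentiment. Given a stream of posts each labelled favourable (F),
contrary (C) or undecided (U) toward vaccination (out-of-context posts
removed), the daily polarity proportions form a compositional time series.
`polarwatch` asks two questions of such a series:

* **Short-term disorientation** — do the daily proportions jump around more
  than multinomial sampling noise allows, as they would if the public kept
  changing its mind in response to contradictory messaging?
* **Long-term disorientation** — once day-to-day noise is smoothed away, is
  there a slow, large-amplitude wave in the favourable share over the year?

The hesitant share is summarised as C + U.

## Day-level multinomial tests

Let $(n_{F,t}, n_{C,t}, n_{U,t})$ be day $t$'s counts with total $N_t$. The
**basic test** takes as null hypothesis that the day's counts are a
multinomial sample with the *pooled yearly* proportions as parameter; the
**running test** replaces that parameter with the unweighted mean of the
daily proportion vectors over the preceding 15 days (a pooled-count variant
is available via `null_type = "pooled"`). The p-value is the exact
multinomial goodness-of-fit tail: the total null probability of every
composition of $N_t$ no more probable than the observed one, ties included.

Enumeration is $O(N_t^2)$ and is used up to `exact_cap = 2000` posts per
day (about two million compositions); beyond that a seeded Monte-Carlo
estimate with the add-one-rank estimator
$(1 + \#\{P(x^{(s)}) \le P(x_{obs})\})/(1 + S)$ is substituted, which is a
valid p-value for any number of draws $S$ (default $10^4$). The two routes
agree within binomial Monte-Carlo error, and at small $n$ full enumeration
confirms the test is valid up to the discreteness atom — both are asserted
in the test suite.

Numerical conventions:

* A category with null probability zero but a positive observed count makes
  the observation impossible under the null: p-value 0. Categories at zero
  in both are dropped from the support.
* Days with zero volume are skipped, never rejected; the first `window`
  days of the running test are warm-up, and days with fewer than
  `min_history = 5` non-empty days in the window are skipped as
  uninformative (the threshold trades a few extra tested days against
  nulls estimated from almost no data).
* No multiplicity correction is applied. Following surveillance practice,
  `rejection_summary()` reports the rejection-day count next to its null
  expectation $\alpha \times$ (tested days) — e.g. 18.25 days for a full
  year at $\alpha = 0.05$ — and the judgement is the comparison of the two.
  `window_sensitivity()` repeats the running tests over alternative window
  lengths since 15 days is a convention, not an estimate.

The **running-variance test** monitors the trailing 15-day sample variance
$s_w^2$ of the favourable proportion against the yearly variance
$\sigma_0^2$ (sample variance over all non-empty days) with the standard
chi-square statistic $T = (w-1)s_w^2/\sigma_0^2$ and a two-sided p-value
$2\min\{F_{\chi^2_{w-1}}(T), 1 - F_{\chi^2_{w-1}}(T)\}$: both abnormally
volatile and abnormally frozen stretches are of interest. The chi-square
reference treats the daily proportions as approximately Gaussian and the
yearly variance as known; both are idealisations, and the calibration of
the resulting rejection fraction is checked by simulation rather than
assumed.

## Long-term trend: discrete beta-kernel smoothing

Symmetric kernels leak weight outside the observed year and bias the
smooth near its boundaries. We therefore smooth on the rescaled day grid
$j/T \in [0,1]$ with a beta-density kernel: the weight of day $j$ for
estimation at day $x$ is proportional to
$f_{\mathrm{Beta}}\!\left(j/T;\; \tfrac{x}{Th}+1,\; \tfrac{T-x}{Th}+1\right)$,
normalised over $j = 0..T$. The shape parameters keep the kernel mode at
$x/T$ — exactly on the boundary when $x$ is 0 or $T$ — and the support
never extends beyond the grid. As $h \to 0$ the weights collapse onto day
$x$ itself. Each category is smoothed with the same weights, so smoothed
proportions of fully observed simplex data still sum to one exactly;
`renormalize = TRUE` restores the simplex when zero-volume days (excluded
from the weighted means rather than imputed) break that identity. The
parametrisation follows the Chen-style boundary-free beta kernel adapted
to a discrete grid; the binding contract is non-negativity, normalisation,
in-support weights and edge modes, all asserted in the tests.

The bandwidth is chosen by leave-one-out cross-validation: each observed
day is predicted with its own weight zeroed and the squared prediction
error summed over days and categories; ties break toward the larger
(smoother) bandwidth. For white noise this pushes $h$ to the top of the
grid (the global mean is the best predictor); for smooth signals it
settles at small-to-moderate values.

`fit_polynomial_trend()` then runs OLS of the smoothed favourable share on
a centred and scaled day index for degrees $0..5$ and selects the smallest
degree $d \ge 1$ whose successor improves $R^2$ by less than
`delta_r2 = 0.01` — an operational reading of "higher degrees help only
negligibly". One percentage point of $R^2$ is small against the jump a
genuine curvature produces (typically tens of points) yet above the gain
spurious high-degree terms extract from a year of smoothed noise.
Coefficients are reported both in the scaled basis (numerically stable)
and re-expanded in raw day units.

## Annotation agreement

Training labels for polarity classifiers come from human annotators, and
their quality bounds everything downstream. For a batch of items each
rated by the same number of raters, `fleiss_kappa()` computes the standard
chance-corrected multi-rater agreement; `pairwise_accuracy()` computes raw
agreement over designed duplicate pairs with a Clopper–Pearson exact
interval (exact because the pair counts are small and a proportion CI
should not rely on asymptotics here). Reproducing any particular published
agreement value would need the underlying annotation data; the functions
are validated against hand computations and simulation extremes instead.

## The synthetic study conditions

Real labelled corpora of this kind cannot be redistributed, so the package
carries a generator whose *default scenario is fixed once* and plays the
role of the study data:

* **365 days** from 2018-01-01; baseline polarity $(0.70, 0.164, 0.136)$.
* **Volumes**: negative binomial, mean 200 (a desk-scale workload; one
  year runs in under a second), dispersion `size = 5`, so days vary
  severalfold around the mean. Three multiplicative spikes (×30, ×60,
  ×45) on days 173, 216 and 248 reproduce the shape of an activity series
  dominated by a few political flashpoints, the August one largest.
* **Events**: short additive shifts of the favourable share (+0.017 for 3
  days, +0.077 for 5 days, +0.036 for 3 days) at the spike days — moderate
  perturbations of the kind seen on peak days. The complement is rescaled
  proportionally so C:U stays fixed.
* **Trend**: a quadratic on the *logit* of the favourable share over
  normalised time, coefficients $(-0.094, 0.910, -1.066)$: the share rises
  from about 68% to a vertex of about 72% some 43% through the year, then
  falls to about 64.5% — a 7–8 point loss from the peak. Working on the
  logit scale keeps every daily probability vector inside the simplex
  without clipping; the cost is that the truth is only approximately
  polynomial in time, which is why trend-recovery checks compare against
  the OLS projection of the noiseless trajectory (the estimand of the
  fitted polynomial) rather than the logit coefficients.
* **Posts**: the daily series is expanded into individual records with
  unique ids, within-day timestamps, an out-of-context fraction of 0.578
  (so roughly 42% of posts are retained, as in the motivating corpus
  scale), a 2% duplicate-record rate to exercise deduplication, and
  per-day like/retweet totals from a lognormal(1, 1) multiplier
  distributed over the day's retained posts. Aggregating the deduplicated
  records reproduces the daily series exactly.

Scenarios shorter than a year default to no spikes and no events, since
the standard-year calendar does not transfer.

What the generator deliberately does **not** model: user-level behaviour
(a heavy-tailed tweeter activity distribution, follower networks, echo
chambers), text, serial correlation of daily proportions beyond the
injected events and trend, and interaction-day attribution of likes (they
are credited to the posting day). Passing calibration and power checks on
these conditions therefore says the *statistics* behave as designed on
data satisfying their assumptions — not that real streams satisfy those
assumptions.

## Verification at a glance

The test suite ties every claim above to a computation: exact-vs-oracle
enumeration and exact-vs-Monte-Carlo equivalence for the multinomial
p-values; full-enumeration validity at small $n$; a 200-replicate null
calibration of the basic test against the 18.25-day benchmark; a
calibration of the running-variance rejection fraction on iid Gaussian
proportions; smoother contracts (constant preservation to $10^{-12}$,
normalisation, in-support weights, identity limit); quadratic-trend
recovery with nominal-rate CI coverage of the projected truth; and a
power study in which 10-day shifts of +0.15 in the favourable share at
volume 500 are flagged by the running test on well over half the event
days while quiet days reject at about the nominal 5%. For the power
study, "quiet" excludes the window after each event: the running null is
contaminated there and the test correctly flags the return to baseline —
a property of running nulls worth remembering when reading real output.

## Limitations

* The exact test is conservative at very low daily volumes (discreteness);
  skipped and low-volume days are reported, not hidden.
* The running null is estimated, not known; immediately after a true
  shift it is contaminated by it, so rejection clusters can trail events.
* The variance test inherits the Gaussian approximation of proportions;
  at tiny volumes its nominal level degrades.
* Bandwidth selection by LOO assumes roughly independent daily errors;
  strong autocorrelation beyond the modelled trend would undersmooth.
* No causal claims: flagged days and fitted trends describe the series,
  not the reasons behind it.
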