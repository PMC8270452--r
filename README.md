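# polarwatch

Surveillance of opinion-polarity time series for collective
**disorientation** — the statistical signature of a public that keeps
changing its mind. The motivating application is vaccine-hesitancy
monitoring on social media: each post is labelled favourable (F), contrary
(C) or undecided (U) toward vaccination, and the daily label proportions
form a compositional time series. `polarwatch` provides the ingestion,
testing, smoothing and simulation machinery to ask whether that series is
merely noisy — or disoriented.

## The statistics at the core

**Short-term disorientation** is probed with three day-level tests:

* *Basic multinomial test*: day $t$'s counts $(n_{F,t}, n_{C,t}, n_{U,t})$
  are tested against $\mathrm{Multinomial}(N_t, \pi^{year})$ where
  $\pi^{year}$ is the pooled yearly proportion vector. The p-value is the
  exact multinomial tail $\sum_{x:\,P(x) \le P(x_{obs})} P(x)$ (full
  enumeration up to 2000 posts/day, seeded Monte Carlo above).
* *Running multinomial test*: the same test with the null rebuilt each day
  from the mean daily proportion vector of the preceding 15 days, which
  catches fast opinion shifts that the yearly null would average away.
* *Running-variance test*: the trailing 15-day variance $s_w^2$ of the
  favourable share is compared with the yearly variance $\sigma_0^2$ via
  $T = (w-1)s_w^2/\sigma_0^2 \sim \chi^2_{w-1}$, two-sided, flagging both
  agitation and abnormal freezing.

Because one test is run per day, results are summarised as *rejection days
versus expectation*: a calibrated test at $\alpha = 0.05$ should flag about
18 of 365 days (exactly 18.25) by chance alone.

**Long-term disorientation** is characterised by smoothing the daily
proportions with a *discrete beta kernel* — weights
$w_j(x) \propto f_{Beta}(j/T;\, x/(Th)+1,\, (T-x)/(Th)+1)$ on the rescaled
day grid, so no weight leaves the observed year and there is no boundary
bias — with the bandwidth chosen by leave-one-out cross-validation, then
fitting polynomials of increasing degree and keeping the smallest degree
after which the $R^2$ gain is below 0.01.

Inter-annotator agreement for the upstream labelling is quantified with
Fleiss' kappa and exact-binomial pairwise accuracy. A fully seeded
synthetic generator (baseline mix, volume spikes, short events, logit-scale
quadratic trend, OOC and duplicate posts) stands in for data that cannot be
redistributed and drives all calibration and power checks.

## Worked example

A year of synthetic posts under the default scenario (three volume spikes
with moderate event shifts, plus a slow parabolic trend in the favourable
share):

```r
library(polarwatch)
cfg <- scenario_config(seed = 1)
gs  <- generate_series(cfg)

polarity_summary(gs$series, seed = 1)
#> Pooled polarity proportions (n = 99612 posts)
#>   F =  72.3%  (95% CI: 72.1-72.6)
#>   C =  15.3%  (95% CI: 15.0-15.5)
#>   U =  12.4%  (95% CI: 12.2-12.6)
#>   hesitant (C + U) = 27.7%  (CI: 27.4-27.9)

rejection_summary(basic_daily_test(gs$series, seed = 1))
#> Rejection-day summary (365 tested days)
#>   alpha = 0.10:  83 rejected vs 36.50 expected
#>   alpha = 0.05:  45 rejected vs 18.25 expected
#>   alpha = 0.01:  23 rejected vs 3.65 expected

rejection_summary(running_daily_test(gs$series, window = 15, seed = 1))
#> Rejection-day summary (350 tested days)
#>   alpha = 0.10:  54 rejected vs 35.00 expected
#>   alpha = 0.05:  29 rejected vs 17.50 expected
#>   alpha = 0.01:   7 rejected vs 3.50 expected

h  <- cv_bandwidth(gs$series, exp(seq(log(0.001), log(0.2), length.out = 25)))
sm <- smooth_series(gs$series, as.numeric(h))
fit_polynomial_trend(sm$smooth_F)
#> Stepwise polynomial trend: degree 2 selected (n = 365)
#>   R-squared by degree: 0: 0.0000, 1: 0.2783, 2: 0.9886, 3: 0.9921, ...
#>   coefficients (raw day index):
#>          x^0          x^1          x^2
#>  6.86670e-01  4.95907e-04 -1.61526e-06
```

Reading the output: the pooled mix is about 72/15/12 with a hesitant share
of 28%. The basic test flags 45 days at the 5% level against the 18.25
expected under stability — short-term disorientation — and the running
test still flags 29 of 350, concentrated around the injected events. The
stepwise fit picks the parabola (the linear fit explains 28% of the
smoothed variance, the quadratic 99%), whose vertex
$-b/(2c) \approx$ day 154 reproduces the generator's spring peak in the
favourable share.

The pipeline can also be driven in one call (`run_config()` +
`run_analysis()`, writing `daily.csv`, per-test CSVs, `smoothed.csv`,
`trend.json`, `summary.json` and a seed-stamped `run.log`), or from a
shell via the thin dispatcher in `inst/cli/polarwatch`
(`simulate | ingest | test | smooth | run`).

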