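# svyjoinpoint

Joinpoint (segmented) trend regression for complex survey data.

Joinpoint regression models a time trend as a continuous piecewise-linear
function on a link scale (log for positive continuous outcomes, logit for
binary ones) and asks two questions: *how many* times did the trend change
slope, and *when*.  Standard joinpoint software assumes independent
observations (or independent yearly summary statistics).  Health-survey
data violate both assumptions: respondents are drawn in clusters (PSUs)
within strata with unequal weights, and when sampled clusters are revisited
across years the yearly estimates are correlated.  Ignoring the design
makes the model-selection criterion anti-conservative — spurious joinpoints
are "detected" because the effective information in the sample is
overstated.

This package implements design-aware joinpoint estimation and selection:

- **Individual-level fitting** of survey-weighted log-normal or logistic
  joinpoint models on microdata, with Taylor-linearization (sandwich)
  variance estimation honouring strata, PSUs and weights.  Fitting uses
  sufficient statistics on (stratum, PSU, time) cells, so a grid search
  over joinpoint locations costs O(cells), not O(records), while remaining
  exactly equal to the record-level fit.
- **Design-adjusted model selection** by a modified design-based AIC
  (m.dAIC): a (scaled) deviance fit term plus the penalty
  `2(2k+1)·δ̄`, where `δ̄` is the average design effect
  `trace(Ĵ⁻¹V̂)/p` comparing the sandwich covariance `V̂` with the
  model-based covariance `Ĵ`.  Two routes are provided: *constrained*
  (design effect from the continuity-constrained model) and
  *unconstrained* (from a per-segment parameterization, mapped back by the
  reparameterization Jacobian `A_k` and evaluated without the intercept).
- **Aggregate-level fitting** of yearly weighted estimates by generalized
  least squares, with the full cross-year covariance of the estimates
  (including covariances induced by PSUs that appear in several years)
  estimated from the microdata, and model selection by a weighted-BIC.
- **Trend summaries**: per-segment annual percent change (APC) and average
  annual percent change (AAPC) with design-df confidence intervals.
- **A simulation harness** that generates finite target populations with
  controllable intracluster correlation (ICC), draws repeated overlapping
  cluster samples, and tallies correct-identification rates for all four
  method variants, plus an SE-vs-empirical-SD comparison study.

## Worked example

Simulate a clustered population whose log-scale trend changes slope in
2006 (APC +0.5% before, −3.6% after), draw one survey sample, and fit:

```r
library(svyjoinpoint)

sc <- jp_scenario(icc = 0.075, apc_diff = -4.1, rate = 0.05,
                  n_clusters = 200, cluster_size = 200,
                  clusters_per_year = 16)
pop  <- simulate_population(sc, seed = 1)
df   <- draw_survey_sample(pop, seed = 7)$records

fit <- svyjoinpoint(y ~ time, data = df, weights = ~weight,
                    strata = ~stratum, psu = ~psu, link = "lognormal")
fit
```

```
Survey-weighted joinpoint regression

Joinpoint selection by m.dAIC (constrained approach, lognormal link)
 k           taus     fit_stat delta_bar    m_daic
 0                -0.123909762  15.92481 -10030.35
 1           2006 -0.005487921  15.74424 -10324.03
 2      1999,2006 -0.004414003  17.13560 -10250.56
 3 1999,2006,2010 -0.003863964  18.76885 -10160.90
Chosen: k = 1 at 2006

Per-segment APC (%), t df = 31:
 from   to   slope     se     apc   lower   upper
 1997 2006  0.0081 0.0017  0.8100  0.4683  1.1529
 2006 2016 -0.0387 0.0013 -3.7938 -4.0555 -3.5313
AAPC over [1997, 2016]: -1.64% (-1.843%, -1.436%)
```

The selection table shows the design effects δ̄ of 15–19: the criterion
charges each extra parameter roughly sixteen independent-data parameters'
worth of penalty, which is what prevents the near-identical fit statistics
of k = 1, 2, 3 from drifting the choice upward.  `summary()`, `coef()`,
`predict()` and `plot()` behave as for other R model objects.  Lower-level
entry points (`svytrend_data()`, `select_joinpoints()`, `yearly_series()`,
`wbic_select()`, `trend_summary()`) expose each stage.

## Command-line interface

`inst/cli/svyjoinpoint.R` wraps three commands:

```sh
Rscript inst/cli/svyjoinpoint.R fit      --input data.csv --link lognormal --approach both
Rscript inst/cli/svyjoinpoint.R simulate --icc 0.075 --apc-diff -4.1 --reps 5 --seed 1
Rscript inst/cli/svyjoinpoint.R reproduce table1 --icc 0.075 --rate 0.05 --apc-diff -4.1 --reps 50
```

Flags may also be supplied via `--config file` (flat `key = value` lines;
flags override the file).  Configuration and schema errors exit with
status 2; every run writes a `manifest.txt` with the effective
configuration.

## License

MIT (see `LICENSE`).
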