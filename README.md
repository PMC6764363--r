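# phenodate

Estimators of phenological transition dates — the onset, peak, and end of
flowering — from **status-based observations**: records that say only whether
open flowers were *present* or *absent* for a plant on a given day of year
(DOY). This is the data structure of herbarium specimens, citizen-science
portals, and most monitoring networks, and the choice of estimator drives
both the bias of the recovered dates and how often an estimate can be made
at all.

The package is aimed at phenologists and ecoinformaticians who need to (a)
estimate transition dates from their own presence/absence records and (b)
understand how those estimates degrade with sample size and sampling bias.

## What it implements

Eight estimators, applicable at the population scale (all plants of a year
pooled) and/or the individual-plant scale:

| Estimator | Data used | Metrics |
|---|---|---|
| First / Last Observed | presences only | onset / end |
| Midway, Midway 7-Day | both | onset, end (individual) |
| Mean Midway, Mean Midway 7-Day | both | onset, end (population) |
| Weibull optimal linear endpoint | presences only | onset, end |
| Logistic threshold crossing | both | onset, end |
| Binomial GAM (thin plate spline) | both | onset, peak, end |
| Kaplan–Meier median | both | peak |
| Mean Flowering date | presences only | peak |

The Weibull estimator is the optimal-linear-endpoint construction used to
date extinctions from sighting records: with distinct ordered presence dates
\(T_{(1)}, \dots, T_{(k)}\) (indexed from the relevant extreme), the endpoint
is \(\hat\theta = \sum_i \lambda_i T_{(i)}\) with weights
\(\lambda = \Lambda^{-1}e / (e'\Lambda^{-1}e)\),
\(\Lambda_{ij} = \Gamma(2\hat v + j)\Gamma(\hat v + i) / (\Gamma(\hat v +
j)\Gamma(i))\) for \(i \le j\), and Weibull tail shape \(\hat v\) estimated
from the gaps to the extreme. The logistic and GAM estimators fit binomial
regressions of status on DOY, evaluate the expected flowering probability on
DOY 1–365, and read the transition off a probability threshold
(0.05/0.25/0.50/0.75/0.95; the threshold with the highest R² is selected per
scenario). The Kaplan–Meier estimator treats absences as right-censored
"not yet flowering" records and returns the median flowering time.

Around the estimators sits a Monte Carlo evaluation pipeline: a synthetic
flowering population with known schedules (286 plants × 11 years by
default, right-skewed daily flower-count curve), randomized status sampling
with exact sample size and presence-fraction composition, and scenario
summaries (R², median signed error, 95% error quantile range, usable rate,
selected threshold, sub-1%-usable exclusion flags). The methods vignette
(`vignettes/transition-date-estimation.Rmd`) documents the model, the
calibration of the generator, and all numerical conventions.

## Worked example

```r
library(phenodate)

schedules <- generate_schedules(generator_params(seed = 1))
truths <- true_metrics_table(schedules)
head(truths$population, 3)
#>   year onset peak end
#> 1 1995   174  196 226
#> 2 1996   177  200 231
#> 3 1997   173  195 228

# one status sample: 50 observations of 1995, half of them presences
daily <- expand_daily_status(schedules, 1995)
set.seed(42)
obs <- draw_population_sample(daily, n_obs = 50, presence_fraction = 0.5)

estimate_transition(obs, "weibull", "onset")
#> <phenodate_estimate> weibull of flowering onset: DOY 180.0
estimate_transition(obs, "first_observed", "onset")
#> <phenodate_estimate> first_observed of flowering onset: DOY 182.0
estimate_transition(obs, "mean_flowering", "peak")
#> <phenodate_estimate> mean_flowering of flowering peak: DOY 195.1
```

The true 1995 onset is DOY 174: the first observed flower lands 8 days late,
while the Weibull endpoint extrapolates back past the earliest sighting.
Scaling this up to a Monte Carlo comparison (200 replicates per year over
the 11 years, sample size 100, 75% presences):

```r
records <- run_population_experiment(
  schedules, n_obs = 100, presence_fraction = 0.75, n_replicates = 200,
  estimators = c("first_observed", "weibull", "mean_flowering"), seed = 1)
summarize_scenarios(records, truths)
#>        estimator metric usable_rate r_squared median_error q025_error q975_error
#> 1 first_observed  onset           1     0.772         4.00       1.00       8.00
#> 2 mean_flowering   peak           1     0.803         0.56      -2.31       3.28
#> 3        weibull    end           1     0.303        -6.81     -16.85       3.87
#> 4        weibull  onset           1     0.713         2.78      -1.52       6.84
```

First Observed is always late for onset (median +4 days) and its error only
shrinks with more presences; the Weibull endpoint roughly halves that median
bias at the same sample size; Mean Flowering recovers the population peak to
within about half a day. `run_individual_experiment()` does the same at the
single-plant scale, and `run_study()` chains generation, both experiments,
threshold selection, and exclusion rules from one configuration
(`load_config()` / YAML).

A thin command-line front end over the same functions is installed at
`inst/cli/phenodate.R` with subcommands `generate`, `sample`, `estimate`,
and `evaluate`, each taking `--seed`, `--config`, `--out`.

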