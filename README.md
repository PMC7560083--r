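# roadbn

Bayesian-network analysis of driver behaviour and accident severity by
driving-license status.

## What it is for

Traffic-safety analysts study *regulatory alignment* — how well drivers'
on-road behaviour complies with the rules the licensing system enforces —
by comparing drivers with valid, invalid and unreported license status.
`roadbn` implements that analysis end to end on driver-level categorical
accident records (one row per driver involved in an accident: license
status, age band, gender, four unsafe-behaviour variables, accident type
and severity):

* a **discrete Bayesian network** over the nine study variables, with the
  joint distribution factorised as
  `P(X1,…,Xn) = ∏ P(Xi | Parents(Xi))` and parameters estimated by
  Laplace-smoothed maximum likelihood (`fit_bn()`);
* **exact posterior queries** `P(objective | evidence)` by variable
  elimination, cross-checked against an exhaustive-enumeration oracle
  (`posterior_eliminate()`, `posterior_enumerate()`);
* **10-fold cross-validation** of each objective variable's predictions,
  scored per state with one-vs-rest Mann–Whitney AUC (`cross_validate()`,
  `auc_report()`);
* **sensitivity analysis**: initial (prior) vs posterior probabilities of
  every objective state under evidence scenarios — license alone,
  license × age, license × gender (`scenario_posteriors()`,
  `study_sensitivity_tables()`);
* a **two-proportion Z-test**
  `Z0 = (P1 − P2) / sqrt(P1(1−P1)/n1 + P2(1−P2)/n2)` flagging significant
  probability shifts beyond the two-sided ±1.96 limits at 95% confidence
  (`z_statistic()`, `z_significant()`);
* a **synthetic-population generator** calibrated to the published
  2016–2018 aggregate frequencies of the Spanish DGT driver database, with
  known ground truth for every downstream test
  (`default_population_spec()`, `generate_drivers()`).

All user-facing functions take a data frame first and return tibbles, so
the pieces chain with the pipe; fitted networks have `tidy()`/`glance()`
methods and the result tables have `autoplot()` methods.

## Worked example

```r
library(roadbn)
library(dplyr)

spec <- default_population_spec()
data <- generate_drivers(spec, n = 50000, seed = 2024) |> filter_drivers()
#> filter_drivers: removed 7439 of 50000 records outside {car, motorcycle}

tabulate_variable(data, "driving_license")
#> # A tibble: 3 × 6
#>   state   n_2016 n_2017 n_2018 total percentage
#> 1 Valid     7693   7728   7834 23255      54.6
#> 2 Invalid    217    216    222   655       1.54
#> 3 Other     6083   6271   6297 18651      43.8

bn <- fit_bn(default_study_dag(), data, pseudocount = 1)
glance(bn)
#> # A tibble: 1 × 6
#>   n_nodes n_edges n_parameters n_records pseudocount  log_lik
#> 1       9      20          576     42561           1 -264423.

scenario_posteriors(bn, data, scenario_grid("driving_license"),
                    objectives = c("speed_infringement", "accident_severity")) |>
  filter(state %in% c("Yes", "SeriousDeath")) |>
  select(objective, state, initial, scenario, posterior, difference_pp, z0, significant)
#> # A tibble: 6 × 8
#>   objective          state        initial scenario                posterior difference_pp     z0 significant
#> 1 speed_infringement Yes           0.0519 driving_license=Valid      0.0804          2.86 -13.7  TRUE
#> 2 accident_severity  SeriousDeath  0.0823 driving_license=Valid      0.0930          1.07  -4.62 TRUE
#> 3 speed_infringement Yes           0.0519 driving_license=Invalid    0.130           7.77  -5.90 TRUE
#> 4 accident_severity  SeriousDeath  0.0823 driving_license=Invalid    0.177           9.51  -6.34 TRUE
#> 5 speed_infringement Yes           0.0519 driving_license=Other      0.0134          3.84  28.1  TRUE
#> 6 accident_severity  SeriousDeath  0.0823 driving_license=Other      0.0655          1.68   7.47 TRUE
```

Reading the output: in this synthetic population (calibrated to the
published aggregates), the fitted model recovers the unlicensed-driving
signature — the probability of a speed infringement rises from a 5.2%
prior to 13.0% given an invalid license versus 8.0% given a valid one, and
the probability of a serious or fatal outcome rises from an 8.2% prior to
17.7% given an invalid license versus 9.3% given a valid one. Each shift
carries its Z statistic against the prior (with `n1` the full dataset and
`n2` the evidence-matching subset) and the 95%-confidence significance
flag that the published tables mark with an asterisk.

The whole pipeline — generate or load, filter to car/motorcycle drivers,
frequency tables, fit, cross-validate, sensitivity report — runs from one
configuration object:

```r
report <- run_study(study_config(n = 50000, seed = 1))
report$auc                     # per-state cross-validated AUC
report$sensitivity$t07_unsafe_by_license
write_study_report(report, "study_out")
```

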