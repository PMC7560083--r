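# Prior-vs-posterior sensitivity tables with Z-test flags.

spec <- default_population_spec()
data20k <- generate_drivers(spec, 20000, seed = 6)
bn20k <- fit_bn(default_study_dag(), data20k)

test_that("probability_difference reports percentage points to 2 decimals", {
  expect_equal(probability_difference(0.0921, 0.1712), 7.91)
  expect_equal(probability_difference(0.5, 0.5), 0)
  for (s in 1:40) {
    x <- withr::with_seed(s, runif(2))
    expect_equal(probability_difference(x[1], x[2]),
                 probability_difference(x[2], x[1]))
  }
  expect_error(probability_difference(-0.1, 0.5))
})

test_that("initial probabilities are the enumeration marginals", {
  for (s in 1:5) {
    bn <- random_bn(s)
    pri <- initial_probabilities(bn, objectives = bn$dag$nodes[1])
    oracle <- posterior_enumerate(bn, bn$dag$nodes[1])
    expect_equal(pri$prob, oracle$prob, tolerance = 1e-9)
  }
  # a point-mass generative spec has point-mass priors
  dict <- tibble::tibble(variable = c("A", "B"), role = "influential",
                         states = list(c("a1", "a2"), c("b1", "b2")))
  pm <- bayesian_network(
    bn_dag(c("A", "B"), data.frame(from = "A", to = "B")),
    list(A = bn_cpt("A", c("a1", "a2"), prob = c(1, 0)),
         B = bn_cpt("B", c("b1", "b2"), list(A = c("a1", "a2")),
                    rbind(c(0, 1), c(1, 0)))),
    dictionary = dict
  )
  pri <- initial_probabilities(pm, objectives = "B")
  expect_equal(pri$prob, c(0, 1))
})

test_that("fitted priors track the training marginal up to the smoothing effect", {
  data100k <- generate_drivers(spec, 100000, seed = 6)
  bn100k <- fit_bn(default_study_dag(), data100k)
  pri <- initial_probabilities(bn100k, "accident_severity")
  emp <- mean(data100k$accident_severity == "NoneMild")
  expect_lt(abs(pri$prob[pri$state == "NoneMild"] - emp), 1e-3)
})

test_that("license-only scenarios obey the law of total probability exactly", {
  tabs <- scenario_posteriors(bn20k, data20k, scenario_grid("driving_license"))
  lic_prior <- posterior_eliminate(bn20k, "driving_license")
  w <- setNames(lic_prior$prob, paste0("driving_license=", lic_prior$state))
  chk <- tabs |>
    dplyr::group_by(.data$objective, .data$state) |>
    dplyr::summarise(
      prior = dplyr::first(.data$initial),
      mix = sum(.data$posterior * w[.data$scenario]),
      .groups = "drop"
    )
  expect_lt(max(abs(chk$mix - chk$prior)), 1e-9)
})

test_that("scenario columns are normalized and flags match the Z-test", {
  tabs <- scenario_posteriors(bn20k, data20k,
                              scenario_grid(c("driving_license", "age_band")),
                              objectives = c("speed_infringement", "accident_severity"))
  sums <- tabs |>
    dplyr::group_by(.data$objective, .data$scenario) |>
    dplyr::summarise(s = sum(.data$posterior), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
  redo <- z_statistic(tabs$initial, tabs$posterior, tabs$n1, pmax(tabs$n2, 1))
  expect_equal(tabs$z0, redo)
  expect_equal(tabs$significant, z_significant(redo))
  expect_true(all(tabs$n1 == nrow(data20k)))
})

test_that("evidence independent of the objective (by construction) leaves the prior", {
  ind <- spec
  sev_states <- c("NoneMild", "SeriousDeath")
  prior <- c(0.9186, 0.0814)
  n_cfg <- 3 * 5 * 3
  ind$cpts$accident_severity <- bn_cpt(
    "accident_severity", sev_states,
    list(driving_license = c("Valid", "Invalid", "Other"),
         age_band = variable_states(spec$dictionary, "age_band"),
         gender = variable_states(spec$dictionary, "gender")),
    matrix(prior, nrow = n_cfg, ncol = 2, byrow = TRUE)
  )
  bn <- as_bn(ind)
  pri <- initial_probabilities(bn, "accident_severity")
  post <- posterior_eliminate(bn, "accident_severity",
                              c(driving_license = "Invalid"))
  expect_lt(max(abs(post$prob - pri$prob)), 0.005)
})

test_that("impossible scenarios are reported, not dropped", {
  dict <- tibble::tibble(variable = c("driving_license", "accident_severity"),
                         role = c("evidence", "objective_accident"),
                         states = list(c("Valid", "Invalid", "Other"),
                                       c("NoneMild", "SeriousDeath")))
  bn <- bayesian_network(
    bn_dag(c("driving_license", "accident_severity"),
           data.frame(from = "driving_license", to = "accident_severity")),
    list(driving_license = bn_cpt("driving_license", c("Valid", "Invalid", "Other"),
                                  prob = c(0.9, 0.1, 0)), # "Other" never occurs
         accident_severity = bn_cpt("accident_severity", c("NoneMild", "SeriousDeath"),
                                    list(driving_license = c("Valid", "Invalid", "Other")),
                                    rbind(c(0.95, 0.05), c(0.8, 0.2), c(0.5, 0.5)))),
    dictionary = dict
  )
  data <- tibble::tibble(driving_license = c("Valid", "Invalid"),
                         accident_severity = c("NoneMild", "SeriousDeath"))
  tabs <- scenario_posteriors(bn, data, scenario_grid("driving_license", dict))
  other <- tabs[tabs$scenario == "driving_license=Other", ]
  expect_equal(unique(other$status), "impossible_evidence")
  expect_true(all(is.na(other$posterior)))
  expect_equal(nrow(tabs[tabs$status == "ok", ]), 4L)
})

test_that("the fitted sensitivity tables show the unlicensed-driving signature", {
  lic <- scenario_grid("driving_license")
  tabs <- scenario_posteriors(bn20k, data20k, lic,
                              objectives = c("speed_infringement", "accident_severity"))
  cell <- function(obj, st, sc) {
    tabs$posterior[tabs$objective == obj & tabs$state == st &
                     tabs$scenario == paste0("driving_license=", sc)]
  }
  expect_gt(cell("speed_infringement", "Yes", "Invalid"),
            cell("speed_infringement", "Yes", "Valid"))
  expect_gt(cell("accident_severity", "SeriousDeath", "Invalid"),
            cell("accident_severity", "SeriousDeath", "Valid"))
  expect_lt(cell("accident_severity", "NoneMild", "Invalid"),
            cell("accident_severity", "NoneMild", "Valid"))
})

test_that("study_sensitivity_tables returns the eight analysis views", {
  tabs <- study_sensitivity_tables(bn20k, data20k)
  expect_named(tabs, c("t06_safe_by_license", "t07_unsafe_by_license",
                       "t08_behaviors_license_age", "t09_behaviors_license_gender",
                       "t10_type_license_age", "t11_severity_license_age",
                       "t12_type_license_gender", "t13_severity_license_gender"))
  expect_equal(nrow(tabs$t06_safe_by_license), 5 * 3)
  expect_equal(nrow(tabs$t11_severity_license_age), 2 * 15)
  wide <- format_sensitivity(tabs$t06_safe_by_license)
  expect_true("driving_license=Invalid" %in% names(wide))
})
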