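# Variable dictionary, record I/O, vehicle filtering and frequency tabulation.

test_that("dictionary covers the nine study variables and validates", {
  dict <- default_variable_dictionary()
  expect_equal(nrow(dict), 9L)
  expect_setequal(
    dict$variable,
    c("driving_license", "right_of_way_violation", "speed_infringement",
      "other_infringements", "distraction", "accident_type",
      "accident_severity", "age_band", "gender")
  )
  expect_equal(variable_states(dict, "driving_license"),
               c("Valid", "Invalid", "Other"))
  expect_equal(variable_states(dict, "accident_severity"),
               c("NoneMild", "SeriousDeath"))
  expect_equal(dictionary_variables(dict, "evidence"), "driving_license")
  expect_length(dictionary_variables(dict, "objective"), 6L)
  expect_silent(validate_dictionary(dict))

  bad <- dict
  bad$states[[1]] <- c("OnlyOne")
  expect_error(validate_dictionary(bad), "fewer than 2")
  bad <- dict
  bad$variable[2] <- dict$variable[1]
  expect_error(validate_dictionary(bad), "duplicated")
})

test_that("dictionary round-trips through YAML, including the packaged default", {
  dict <- default_variable_dictionary()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_variable_dictionary(dict, path)
  back <- read_variable_dictionary(path)
  expect_equal(back$variable, dict$variable)
  expect_equal(back$states, dict$states)

  shipped <- read_variable_dictionary(
    system.file("extdata", "variable_dictionary.yaml", package = "roadbn")
  )
  expect_equal(shipped$states, dict$states)
  expect_equal(shipped$role, dict$role)
})

test_that("read_drivers reads valid files and enforces the error contract", {
  dict <- default_variable_dictionary()
  path <- withr::local_tempfile(fileext = ".csv")
  data <- generate_drivers(default_population_spec(), n = 3, seed = 4)
  write_drivers(data, path)
  back <- read_drivers(path, dict)
  expect_equal(nrow(back), 3L)
  expect_equal(back$driving_license, data$driving_license)

  # missing column named in the error
  broken <- dplyr::select(data, -"gender")
  write_drivers(broken, path)
  expect_error(read_drivers(path, dict), "gender")

  # unknown state label named with its row
  bad <- data
  bad$driving_license[2] <- "Suspended"
  write_drivers(bad, path)
  expect_error(read_drivers(path, dict), "Suspended.*row 2")
})

test_that("write-then-read round-trips a 1,000-record synthetic dataset", {
  data <- generate_drivers(default_population_spec(), n = 1000, seed = 99)
  path <- withr::local_tempfile(fileext = ".csv")
  write_drivers(data, path)
  back <- read_drivers(path)
  expect_equal(as.data.frame(back), as.data.frame(data), ignore_attr = TRUE)
  # idempotence: a second write-read changes nothing
  write_drivers(back, path)
  again <- read_drivers(path)
  expect_equal(as.data.frame(again), as.data.frame(back), ignore_attr = TRUE)
})

test_that("filter_drivers keeps car/motorcycle records in order and reports removals", {
  data <- tibble::tibble(
    driving_license = c("Valid", "Valid", "Invalid", "Other", "Valid"),
    vehicle_class = c("car", "truck", "motorcycle", "truck", "car")
  )
  expect_message(out <- filter_drivers(data), "removed 2 of 5")
  expect_equal(nrow(out), 3L)
  expect_equal(attr(out, "n_removed"), 2L)
  expect_equal(out$vehicle_class, c("car", "motorcycle", "car"))

  all_car <- dplyr::mutate(data, vehicle_class = "car")
  expect_equal(nrow(suppressMessages(filter_drivers(all_car))), 5L)

  data$vehicle_class[1] <- NA
  expect_error(suppressMessages(filter_drivers(data)), "absent")
  expect_error(filter_drivers(tibble::tibble(x = 1)), "vehicle_class")
})

test_that("filtered count matches the generator's own class tally", {
  data <- generate_drivers(default_population_spec(), n = 5000, seed = 21)
  tally <- attr(data, "generator")$class_tally
  out <- suppressMessages(filter_drivers(data))
  expect_equal(nrow(out), sum(tally[c("car", "motorcycle")]))
})

test_that("tabulate_variable reproduces counts, percentages and denominators", {
  data <- tibble::tibble(
    accident_severity = c("NoneMild", "NoneMild", "SeriousDeath", NA),
    year = c(2016L, 2017L, 2016L, 2016L)
  )
  tab <- tabulate_variable(data, "accident_severity")
  expect_equal(tab$total, c(2L, 1L))
  expect_equal(attr(tab, "denominator"), 3L) # the NA-sentinel record is excluded
  expect_equal(tab$percentage, c(66.67, 33.33))
  expect_equal(tab$n_2016, c(1L, 1L))

  expect_error(tabulate_variable(data, "not_a_variable"), "unknown variable")
})

test_that("tabulate is permutation-invariant and never drops records", {
  data <- generate_drivers(default_population_spec(), n = 2000, seed = 3)
  perm <- withr::with_seed(8, sample.int(nrow(data)))
  for (v in c("driving_license", "distraction", "age_band")) {
    a <- tabulate_variable(data, v)
    b <- tabulate_variable(data[perm, ], v)
    expect_equal(a$total, b$total)
    expect_equal(sum(a$total), nrow(data))
    expect_lt(abs(sum(a$percentage) - 100), 0.05)
  }
})

test_that("empty datasets tabulate to zero counts with undefined percentages", {
  data <- generate_drivers(default_population_spec(), n = 0, seed = 1)
  tab <- tabulate_variable(data, "gender")
  expect_equal(tab$total, rep(0L, 3))
  expect_true(all(is.na(tab$percentage)))
  expect_true(attr(tab, "undefined"))
})

test_that("dataset_from_counts reproduces every reference count exactly", {
  counts <- dgt_reference_counts()
  data <- dataset_from_counts(counts)
  expect_equal(nrow(data), 467431L)
  for (v in c("driving_license", "accident_type", "gender")) {
    tab <- tabulate_variable(data, v)
    ref <- counts |>
      dplyr::filter(.data$variable == v) |>
      dplyr::group_by(.data$state) |>
      dplyr::summarise(n = sum(.data$n))
    expect_equal(tab$total[match(ref$state, tab$state)], ref$n)
  }
  # the accident factors use their own, smaller denominator
  expect_equal(attr(tabulate_variable(data, "accident_severity"), "denominator"),
               467279L)
  expect_equal(attr(tabulate_variable(data, "driving_license"), "denominator"),
               467431L)
})
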