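# Driver-record datasets: reading, writing, filtering, frequency tabulation.

#' Published aggregate frequency counts of the Spanish DGT driver database
#'
#' Per-state, per-year counts of drivers involved in traffic accidents in
#' Spain (2016--2018), as published in aggregate for the filtered car- and
#' motorcycle-driver database (467,431 drivers; 467,279 for the two
#' accident-factor variables, whose tabulation covers slightly fewer records).
#' These counts calibrate the synthetic-population generator and let the
#' frequency-tabulation code be checked against the published percentages.
#'
#' @return A tibble with columns `variable`, `state`, `year` and `n`.
#' @examples
#' dgt_reference_counts() |> dplyr::filter(variable == "driving_license")
#' @export
dgt_reference_counts <- function() {
  path <- system.file("extdata", "dgt_reference_counts.csv", package = "roadbn")
  counts <- readr::read_csv(
    path,
    col_types = readr::cols(
      variable = readr::col_character(),
      state = readr::col_character(),
      year = readr::col_integer(),
      n = readr::col_integer()
    ),
    progress = FALSE
  )
  counts
}

#' Expand aggregate counts into a driver-level dataset
#'
#' Builds a driver-level tibble whose per-year, per-state marginal counts equal
#' `counts` exactly. The joint arrangement across variables is arbitrary (and
#' deterministic): within each year every variable's column is filled with its
#' states in dictionary order, padded with the `NA` "absent" sentinel up to the
#' year's record total, so variables tabulated over fewer records (the
#' accident factors) come out with their own, smaller denominator.
#'
#' Only marginal tabulations of the result are meaningful; it carries no
#' dependence structure.
#'
#' @param counts A tibble as returned by [dgt_reference_counts()].
#' @param dict A variable dictionary.
#' @return A driver-level tibble with one column per dictionary variable plus
#'   `year`.
#' @export
dataset_from_counts <- function(counts, dict = default_variable_dictionary()) {
  stopifnot(all(c("variable", "state", "year", "n") %in% names(counts)))
  years <- sort(unique(counts$year))
  per_year <- purrr::map(years, function(y) {
    cy <- counts[counts$year == y, , drop = FALSE]
    n_year <- max(vapply(
      split(cy$n, cy$variable), sum, numeric(1)
    ))
    cols <- purrr::map(dict$variable, function(v) {
      cv <- cy[cy$variable == v, , drop = FALSE]
      states <- variable_states(dict, v)
      cv <- cv[order(match(cv$state, states)), , drop = FALSE]
      bad <- setdiff(cv$state, states)
      if (length(bad)) {
        stop("counts for '", v, "' contain unknown state(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      c(rep(cv$state, cv$n), rep(NA_character_, n_year - sum(cv$n)))
    })
    names(cols) <- dict$variable
    tibble::as_tibble(cols) |> dplyr::mutate(year = as.integer(y))
  })
  dplyr::bind_rows(per_year)
}

#' Read a driver-level dataset from delimited text
#'
#' Reads a headered CSV of categorical driver records and validates every
#' value against the dictionary. `year` and `vehicle_class` columns are
#' optional passthrough tags. Empty fields become the `NA` "absent" sentinel,
#' which is distinct from an explicit "Unknown" state.
#'
#' @param path Path to a CSV file with one row per driver.
#' @param dict A variable dictionary.
#' @return A driver-level tibble.
#' @section Errors: a dictionary variable missing from the header is a hard
#'   error naming the column; a value that is not a listed state of its
#'   variable is a hard error naming the variable, value and data row.
#' @export
read_drivers <- function(path, dict = default_variable_dictionary()) {
  data <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  missing <- setdiff(dict$variable, names(data))
  if (length(missing)) {
    stop("dataset is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if ("year" %in% names(data)) data$year <- as.integer(data$year)
  validate_drivers(data, dict)
  data
}

#' @rdname read_drivers
#' @param data A driver-level tibble.
#' @export
write_drivers <- function(data, path) {
  readr::write_csv(data, path, na = "")
  invisible(path)
}

#' Validate driver records against the dictionary
#'
#' @inheritParams read_drivers
#' @return `data`, invisibly.
#' @export
validate_drivers <- function(data, dict = default_variable_dictionary()) {
  for (v in intersect(dict$variable, names(data))) {
    states <- variable_states(dict, v)
    vals <- data[[v]]
    bad <- !is.na(vals) & !(vals %in% states)
    if (any(bad)) {
      row <- which(bad)[1L]
      stop("unknown state label '", vals[row], "' for variable '", v,
           "' at data row ", row, call. = FALSE)
    }
  }
  invisible(data)
}

#' Restrict a dataset to car and motorcycle drivers
#'
#' Mirrors the study's filtering of the national drivers database down to car
#' and motorcycle drivers. Record order is preserved and the number of removed
#' records is reported (message and `n_removed` attribute).
#'
#' @param data A driver-level tibble with a `vehicle_class` column; a missing
#'   column or an `NA` class on any record is a hard error.
#' @param keep Vehicle classes retained; default `c("car", "motorcycle")`.
#' @return The filtered tibble.
#' @export
filter_drivers <- function(data, keep = c("car", "motorcycle")) {
  if (!"vehicle_class" %in% names(data)) {
    stop("filter_drivers() requires a 'vehicle_class' column", call. = FALSE)
  }
  if (anyNA(data$vehicle_class)) {
    stop("vehicle_class is absent (NA) on ", sum(is.na(data$vehicle_class)),
         " record(s); every record must carry a vehicle class", call. = FALSE)
  }
  out <- data[data$vehicle_class %in% keep, , drop = FALSE]
  n_removed <- nrow(data) - nrow(out)
  message("filter_drivers: removed ", n_removed, " of ", nrow(data),
          " records outside {", paste(keep, collapse = ", "), "}")
  attr(out, "n_removed") <- n_removed
  out
}

# Half-up decimal rounding, matching the print convention of the published
# tables (R's round() rounds half to even). The 1e-9 nudge absorbs binary
# representation error just below a .5 boundary.
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  floor(x * scale + 0.5 + 1e-9) / scale
}

#' Tabulate a variable's frequencies
#'
#' Per-state counts (by year when a `year` column is present), state totals and
#' percentages of the variable's own non-absent total, reported to 2 decimals
#' with half-up rounding -- the layout of the published frequency tables. The
#' denominator is the number of records with a non-`NA` value for *this*
#' variable, so variables tabulated over fewer records keep their own total.
#'
#' @param data A driver-level tibble.
#' @param variable Variable to tabulate; must exist in `dict`.
#' @param dict A variable dictionary.
#' @return A `frequency_table` tibble with columns `state`, one `n_<year>`
#'   column per year (if year tags are present), `total` and `percentage`,
#'   plus attributes `variable` and `denominator`. On an empty denominator the
#'   percentages are `NA` and the table carries `undefined = TRUE`.
#' @examples
#' counts <- dgt_reference_counts()
#' data <- dataset_from_counts(counts)
#' tabulate_variable(data, "driving_license")
#' @export
tabulate_variable <- function(data, variable, dict = default_variable_dictionary()) {
  if (!variable %in% dict$variable) {
    stop("unknown variable '", variable, "'", call. = FALSE)
  }
  if (!variable %in% names(data)) {
    stop("dataset is missing column(s): ", variable, call. = FALSE)
  }
  states <- variable_states(dict, variable)
  vals <- data[[variable]]
  keep <- !is.na(vals)
  base <- tibble::tibble(state = factor(vals[keep], levels = states))
  years <- if ("year" %in% names(data)) sort(unique(data$year[!is.na(data$year)])) else integer(0)
  if (length(years)) {
    base$year <- data$year[keep]
    tab <- base |>
      dplyr::count(.data$state, .data$year) |>
      tidyr::complete(state = factor(states, levels = states),
                      year = years, fill = list(n = 0L)) |>
      dplyr::filter(!is.na(.data$year)) |>
      tidyr::pivot_wider(names_from = "year", values_from = "n",
                         names_prefix = "n_")
  } else {
    tab <- base |> dplyr::count(.data$state, .drop = FALSE)
    names(tab)[names(tab) == "n"] <- "n_total"
  }
  count_cols <- setdiff(names(tab), "state")
  tab$total <- as.integer(rowSums(tab[count_cols]))
  denom <- sum(tab$total)
  tab$percentage <- if (denom > 0) round_half_up(tab$total / denom * 100, 2) else NA_real_
  tab$state <- as.character(tab$state)
  tab <- tab[match(states, tab$state), , drop = FALSE]
  attr(tab, "variable") <- variable
  attr(tab, "denominator") <- denom
  attr(tab, "undefined") <- denom == 0
  class(tab) <- c("frequency_table", class(tab))
  tab
}

#' Tabulate a group of variables into one long table
#'
#' @param data A driver-level tibble.
#' @param variables Variables to tabulate.
#' @param dict A variable dictionary.
#' @return A tibble stacking [tabulate_variable()] outputs with a leading
#'   `variable` column.
#' @export
tabulate_variables <- function(data, variables, dict = default_variable_dictionary()) {
  purrr::map(variables, function(v) {
    tab <- tabulate_variable(data, v, dict)
    tibble::as_tibble(tab) |>
      dplyr::mutate(variable = v, denominator = attr(tab, "denominator"),
                    .before = 1)
  }) |> dplyr::bind_rows()
}
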