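#' The study variable dictionary
#'
#' The nine categorical variables of the driver-level analysis, their ordered
#' state labels and their role in the model:
#'
#' * `evidence` -- `driving_license` (Valid / Invalid / Other). "Invalid" covers
#'   expired, canceled, suspended or never-obtained licenses, an inappropriate
#'   class, or a total loss of points; "Other" marks accident reports where the
#'   license information is incomplete.
#' * `influential` -- the demographic variables `age_band` and `gender`.
#' * `objective_behavior` -- the four unsafe-behaviour variables
#'   (`right_of_way_violation`, `speed_infringement`, `other_infringements`,
#'   `distraction`).
#' * `objective_accident` -- `accident_type` and `accident_severity`.
#'
#' "Unknown" is an ordinary, explicitly listed state wherever the source
#' tabulations report one; it is not treated as missing data. A genuinely
#' absent value (a record not covered by a variable's tabulation) is the `NA`
#' sentinel, distinct from "Unknown".
#'
#' @return A tibble with one row per variable and columns `variable`, `role`
#'   and `states` (a list-column of ordered state labels).
#' @examples
#' default_variable_dictionary()
#' @export
default_variable_dictionary <- function() {
  dict <- tibble::tribble(
    ~variable,              ~role,                 ~states,
    "driving_license",      "evidence",            c("Valid", "Invalid", "Other"),
    "age_band",             "influential",         c("<25", "25-40", "41-60", ">60", "Unknown"),
    "gender",               "influential",         c("Men", "Women", "Unknown"),
    "right_of_way_violation", "objective_behavior", c("No", "Yes", "Unknown"),
    "speed_infringement",   "objective_behavior",  c("No", "Yes", "Unknown"),
    "other_infringements",  "objective_behavior",  c("No", "Yes", "Unknown"),
    "distraction",          "objective_behavior",  c("No", "Technology", "Other", "Unknown"),
    "accident_type",        "objective_accident",  c("Collision", "RunOver", "Other"),
    "accident_severity",    "objective_accident",  c("NoneMild", "SeriousDeath")
  )
  class(dict) <- c("variable_dictionary", class(dict))
  dict
}

#' Validate a variable dictionary
#'
#' Checks the structural invariants: every variable has at least two uniquely
#' labelled states, names are unique, and roles are drawn from the four
#' recognised groups.
#'
#' @param dict A dictionary tibble as returned by
#'   [default_variable_dictionary()].
#' @return `dict`, invisibly, or an error describing the violation.
#' @export
validate_dictionary <- function(dict) {
  stopifnot(is.data.frame(dict), all(c("variable", "role", "states") %in% names(dict)))
  if (anyDuplicated(dict$variable)) {
    stop("duplicated variable names in dictionary", call. = FALSE)
  }
  roles <- c("evidence", "influential", "objective_behavior", "objective_accident")
  bad_role <- setdiff(dict$role, roles)
  if (length(bad_role)) {
    stop("unrecognised role(s): ", paste(bad_role, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(dict))) {
    st <- dict$states[[i]]
    if (length(st) < 2L) {
      stop("variable '", dict$variable[i], "' has fewer than 2 states", call. = FALSE)
    }
    if (anyDuplicated(st)) {
      stop("variable '", dict$variable[i], "' has duplicated state labels", call. = FALSE)
    }
  }
  invisible(dict)
}

#' Look up the ordered states of a variable
#'
#' @param dict A variable dictionary.
#' @param variable Variable name.
#' @return Character vector of state labels in canonical order.
#' @export
variable_states <- function(dict, variable) {
  i <- match(variable, dict$variable)
  if (is.na(i)) stop("unknown variable '", variable, "'", call. = FALSE)
  dict$states[[i]]
}

#' List dictionary variables, optionally by role
#'
#' @param dict A variable dictionary.
#' @param role Optional role filter; one or more of `"evidence"`,
#'   `"influential"`, `"objective_behavior"`, `"objective_accident"`, or the
#'   shorthand `"objective"` for both objective groups.
#' @return Character vector of variable names.
#' @export
dictionary_variables <- function(dict, role = NULL) {
  if (is.null(role)) return(dict$variable)
  if (identical(role, "objective")) {
    role <- c("objective_behavior", "objective_accident")
  }
  dict$variable[dict$role %in% role]
}

#' Read / write a variable dictionary as YAML
#'
#' The on-disk format is a YAML list of `{variable, role, states}` entries; the
#' canonical dictionary ships with the package at
#' `system.file("extdata", "variable_dictionary.yaml", package = "roadbn")`.
#'
#' @param path File path.
#' @return `read_variable_dictionary()` returns a validated dictionary tibble;
#'   `write_variable_dictionary()` returns `path` invisibly.
#' @export
read_variable_dictionary <- function(path) {
  raw <- yaml::read_yaml(path)
  dict <- tibble::tibble(
    variable = purrr::map_chr(raw, "variable"),
    role = purrr::map_chr(raw, "role"),
    states = purrr::map(raw, function(x) as.character(x$states))
  )
  class(dict) <- c("variable_dictionary", class(dict))
  validate_dictionary(dict)
  dict
}

#' @rdname read_variable_dictionary
#' @param dict A variable dictionary tibble.
#' @export
write_variable_dictionary <- function(dict, path) {
  validate_dictionary(dict)
  entries <- purrr::pmap(dict, function(variable, role, states) {
    list(variable = variable, role = role, states = as.character(states))
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}
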