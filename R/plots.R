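# ggplot2 views of the result tables.

#' Plot a frequency table
#'
#' @param object A `frequency_table` from [tabulate_variable()].
#' @param ... Unused.
#' @return A ggplot: percentage per state.
#' @method autoplot frequency_table
#' @export
autoplot.frequency_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$state <- factor(df$state, levels = df$state)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$state, y = .data$percentage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = attr(object, "variable"), y = "% of records",
      title = paste0("Frequencies of ", attr(object, "variable"),
                     " (n = ", attr(object, "denominator"), ")")
    ) +
    ggplot2::theme_minimal()
}

#' Plot an AUC report
#'
#' @param object An `auc_report` from [auc_report()].
#' @param ... Unused.
#' @return A ggplot: per-state AUC by target with the 0.5 random-prediction
#'   reference line.
#' @method autoplot auc_report
#' @export
autoplot.auc_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$state, y = .data$auc)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::facet_wrap(~target, scales = "free_x") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "one-vs-rest AUC",
                  title = "Cross-validated AUC per objective state") +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity table
#'
#' Posterior probability per scenario against the initial probability
#' (horizontal mark), significant shifts drawn solid.
#'
#' @param object A `sensitivity_table` from [scenario_posteriors()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sensitivity_table
#' @export
autoplot.sensitivity_table <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$status == "ok")
  df$panel <- paste(df$objective, df$state, sep = ": ")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario, y = .data$posterior)) +
    ggplot2::geom_point(ggplot2::aes(alpha = .data$significant)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$initial),
                        linetype = "dotted") +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.35, `TRUE` = 1),
                                na.value = 0.35) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "posterior probability",
                  title = "Prior vs posterior under evidence scenarios",
                  alpha = "significant") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
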