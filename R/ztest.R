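# Two-proportion Z-test deciding whether an initial and a posterior
# probability differ significantly:
#
#   H0: P1 = P2   vs   HA: P1 != P2
#   Z0 = (P1 - P2) / sqrt(P1 (1 - P1) / n1 + P2 (1 - P2) / n2)
#
# where n1 and n2 are the sizes of the populations behind P1 and P2. In the
# sensitivity tables n1 is the full analysis dataset (population of the
# initial probability) and n2 the count of records matching the scenario's
# evidence (population of the posterior).

#' Two-proportion Z statistic
#'
#' @param p1,p2 Proportions in `[0, 1]` (initial and posterior probability).
#' @param n1,n2 Sizes (>= 1) of the populations behind `p1` and `p2`.
#' @return The Z0 statistic (vectorised). When both proportions are
#'   degenerate (each exactly 0 or 1) the variance vanishes and the result is
#'   the undefined flag `NA`, not a number.
#' @examples
#' z_statistic(0.0921, 0.1712, n1 = 253306, n2 = 7057) # about -17.5
#' @export
z_statistic <- function(p1, p2, n1, n2) {
  stopifnot(all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1),
            all(n1 >= 1), all(n2 >= 1))
  v <- p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2
  # both proportions degenerate -> zero variance -> undefined, never Inf/NaN
  ifelse(v > 0, (p1 - p2) / sqrt(v), NA_real_)
}

#' Two-sided critical value at the reported precision
#'
#' The inverse normal quantile for a two-sided level `alpha`, rounded half-up
#' to 2 decimals to match the printed +/-1.96 convention at `alpha = 0.05`.
#'
#' @param alpha Significance level in `(0, 1)`.
#' @return The critical value.
#' @export
z_critical <- function(alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  round_half_up(qnorm(1 - alpha / 2), 2)
}

#' Significance verdict for a Z statistic
#'
#' Significant iff `|Z0|` strictly exceeds the two-sided critical value
#' (1.96 at `alpha = 0.05`): values less than -1.96 or greater than +1.96 are
#' significant differences, the boundary itself is not.
#'
#' @param z Z0 statistic(s).
#' @param alpha Significance level; default 0.05 (95% confidence).
#' @return Logical (vectorised); `NA` for an undefined statistic.
#' @examples
#' z_significant(2.5)   # TRUE
#' z_significant(1.96)  # FALSE: the limit itself is not beyond the limit
#' @export
z_significant <- function(z, alpha = 0.05) {
  abs(z) > z_critical(alpha)
}

#' Tidy two-proportion Z-test
#'
#' @inheritParams z_statistic
#' @param alpha Significance level.
#' @return A tibble with `p1`, `p2`, `n1`, `n2`, `z0`, `critical`,
#'   `significant` (vectorised over the inputs).
#' @export
two_proportion_z_test <- function(p1, p2, n1, n2, alpha = 0.05) {
  z <- z_statistic(p1, p2, n1, n2)
  tibble::tibble(p1 = p1, p2 = p2, n1 = n1, n2 = n2, z0 = z,
                 critical = z_critical(alpha),
                 significant = z_significant(z, alpha))
}
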