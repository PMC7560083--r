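# k-fold cross-validation of the fitted network's predictions of the
# objective variables, scored per state by one-vs-rest AUC.

#' Assign records to k folds
#'
#' Seeded uniform shuffle followed by contiguous blocks; fold sizes differ by
#' at most one and the assignment is deterministic per `(n, k, seed)`.
#'
#' @param n Number of records (`n >= k`).
#' @param k Number of folds (`k >= 2`).
#' @param seed Integer seed for the shuffle.
#' @return Integer vector of fold indices in `1..k`, one per record in
#'   original record order.
#' @export
kfold_split <- function(n, k = 10, seed) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (n < k) stop("cannot split ", n, " records into ", k, " folds", call. = FALSE)
  perm <- withr::with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  fold <- integer(n)
  fold[perm] <- rep.int(seq_len(k), sizes)
  fold
}

#' Cross-validated posterior predictions of target variables
#'
#' For each fold, fits the network on the complement and predicts each target
#' for every held-out record by variable elimination given the record's
#' predictor values; the concatenation over folds covers every record exactly
#' once. A fold whose training data lacks a state entirely is handled by the
#' Laplace pseudocount, not by an error.
#'
#' By default the predictors are the evidence and influential variables
#' (license, age band, gender) -- the same conditioning set as the
#' sensitivity analyses -- and never the other objective variables.
#' Unstratified uniform folds are the default; pass `stratify_by` to balance
#' a variable's states across folds.
#'
#' @param dag A `bn_dag`.
#' @param data A driver-level tibble.
#' @param targets Target (objective) variables to predict.
#' @param k Number of folds.
#' @param seed Seed for the fold shuffle.
#' @param pseudocount Laplace smoothing for the per-fold fits.
#' @param predictors Conditioning variables; default evidence + influential
#'   roles from `dict`.
#' @param stratify_by Optional variable whose states are balanced across
#'   folds.
#' @param dict A variable dictionary.
#' @return A `prediction_set` tibble: `target`, `row` (original record),
#'   `fold`, `truth`, `state`, `prob`; per-record probabilities sum to 1.
#' @export
cross_validate <- function(dag, data, targets, k = 10, seed = 1,
                           pseudocount = 1, predictors = NULL,
                           stratify_by = NULL,
                           dict = default_variable_dictionary()) {
  stopifnot(all(targets %in% dag$nodes))
  if (is.null(predictors)) {
    predictors <- intersect(
      dictionary_variables(dict, c("evidence", "influential")), dag$nodes
    )
  }
  overlap <- intersect(predictors, targets)
  if (length(overlap)) {
    stop("variable(s) cannot be both predictor and target: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  n <- nrow(data)
  if (is.null(stratify_by)) {
    fold <- kfold_split(n, k, seed)
  } else {
    fold <- integer(n)
    strata <- split(seq_len(n), data[[stratify_by]])
    # per-stratum contiguous split with a stratum-specific derived seed
    for (i in seq_along(strata)) {
      idx <- strata[[i]]
      f <- if (length(idx) >= k) kfold_split(length(idx), k, seed + i)
      else withr::with_seed(seed + i, sample(rep_len(seq_len(k), length(idx))))
      fold[idx] <- f
    }
  }
  out <- purrr::map(seq_len(k), function(f) {
    bn <- fit_bn(dag, data[fold != f, , drop = FALSE], pseudocount = pseudocount,
                 dict = NULL)
    test_idx <- which(fold == f)
    configs <- data[test_idx, predictors, drop = FALSE] |>
      dplyr::mutate(row = test_idx)
    unique_cfg <- dplyr::distinct(configs[predictors])
    preds <- purrr::map(seq_len(nrow(unique_cfg)), function(j) {
      ev <- unlist(unique_cfg[j, ])
      ev <- ev[!is.na(ev)]
      purrr::map(targets, function(tg) {
        post <- posterior_eliminate(bn, tg, ev)
        dplyr::bind_cols(unique_cfg[j, ], tibble::tibble(
          target = tg, state = post$state, prob = post$prob
        ))
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
    configs |>
      dplyr::left_join(preds, by = predictors,
                       relationship = "many-to-many") |>
      dplyr::mutate(fold = f)
  }) |> dplyr::bind_rows()
  truth <- purrr::map(targets, function(tg) {
    tibble::tibble(target = tg, row = seq_len(n), truth = data[[tg]])
  }) |> dplyr::bind_rows()
  out <- out |>
    dplyr::left_join(truth, by = c("target", "row"))
  out <- out[c("target", "row", "fold", "truth", "state", "prob")] |>
    dplyr::arrange(.data$target, .data$row)
  class(out) <- c("prediction_set", class(out))
  out
}

#' One-vs-rest AUC (Mann-Whitney)
#'
#' `(concordant pairs + 0.5 * tied pairs) / (positives * negatives)` -- the
#' probability that a randomly chosen positive scores above a randomly chosen
#' negative, with half credit for ties. 0.5 is random prediction, 1 perfect,
#' below 0.5 systematically inverted.
#'
#' @param scores Numeric predicted probability (or any score) per record.
#' @param labels Logical (or 0/1) indicator of the positive state per record.
#' @return AUC in `[0, 1]`, or `NA` when the labels are single-class
#'   (undefined rather than a number).
#' @examples
#' auc_one_vs_rest(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)) # 1
#' @export
auc_one_vs_rest <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores) # average ranks give the 0.5 tie credit
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Per-state AUC report for cross-validated predictions
#'
#' @param predictions A `prediction_set` from [cross_validate()].
#' @return An `auc_report` tibble: `target`, `state`, `n_pos`, `n_neg`,
#'   `auc`.
#' @export
auc_report <- function(predictions) {
  out <- predictions |>
    dplyr::group_by(.data$target, .data$state) |>
    dplyr::summarise(
      n_pos = sum(.data$truth == .data$state),
      n_neg = sum(.data$truth != .data$state),
      auc = auc_one_vs_rest(.data$prob, .data$truth == .data$state),
      .groups = "drop"
    )
  class(out) <- c("auc_report", class(out))
  out
}
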