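# Exact posterior queries P(query | evidence): an exhaustive-enumeration
# oracle and a variable-elimination engine that must agree to 1e-9.
#
# Probabilities are carried in linear space throughout: the networks here are
# a handful of small categorical variables, where underflow is not a risk.

check_query <- function(bn, query, evidence) {
  nodes <- bn$dag$nodes
  if (!query %in% nodes) stop("unknown query variable '", query, "'", call. = FALSE)
  evidence <- unlist(evidence)
  if (length(evidence)) {
    if (is.null(names(evidence)) || any(names(evidence) == "")) {
      stop("evidence must be a named vector/list of variable = state", call. = FALSE)
    }
    bad <- setdiff(names(evidence), nodes)
    if (length(bad)) {
      stop("evidence on unknown variable(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (query %in% names(evidence)) {
      stop("query variable '", query, "' cannot also be evidence", call. = FALSE)
    }
    for (v in names(evidence)) {
      if (!evidence[[v]] %in% bn$cpts[[v]]$states) {
        stop("'", evidence[[v]], "' is not a state of evidence variable '", v, "'",
             call. = FALSE)
      }
    }
  }
  evidence
}

impossible_evidence <- function(evidence) {
  ev <- paste(paste0(names(evidence), "=", unlist(evidence)), collapse = ", ")
  stop(structure(
    class = c("roadbn_impossible_evidence", "error", "condition"),
    list(message = paste0("evidence {", ev, "} has probability 0"),
         call = NULL)
  ))
}

posterior_tibble <- function(bn, query, probs) {
  states <- bn$cpts[[query]]$states
  tibble::tibble(variable = query, state = states,
                 prob = as.numeric(probs[states]))
}

#' Posterior distribution by exhaustive enumeration
#'
#' The brute-force oracle behind the Bayes rule `P(A|B) = P(B|A) P(A) / P(B)`:
#' sums the joint factorisation over all assignments consistent with the
#' evidence. Intended for small networks; the joint state space must not
#' exceed `cap`.
#'
#' @param bn A `driver_bn`.
#' @param query Query variable (must not appear in `evidence`).
#' @param evidence Named character vector/list of observed states; empty for
#'   the marginal prior.
#' @param cap Maximum number of joint states to enumerate (default `1e7`).
#' @return A tibble with columns `variable`, `state`, `prob` summing to 1.
#'   Evidence with probability 0 raises a typed `roadbn_impossible_evidence`
#'   error rather than returning `NaN`.
#' @examples
#' bn <- bayesian_network(
#'   bn_dag(c("A", "B"), data.frame(from = "A", to = "B")),
#'   list(A = bn_cpt("A", c("0", "1"), prob = c(0.5, 0.5)),
#'        B = bn_cpt("B", c("0", "1"), list(A = c("0", "1")),
#'                   rbind(c(0.8, 0.2), c(0.1, 0.9)))))
#' posterior_enumerate(bn, "A", c(B = "1"))
#' @export
posterior_enumerate <- function(bn, query, evidence = NULL, cap = 1e7) {
  evidence <- check_query(bn, query, evidence)
  nodes <- bn$dag$nodes
  card <- vapply(nodes, function(v) length(bn$cpts[[v]]$states), numeric(1))
  if (prod(card) > cap) {
    stop("joint state space (", format(prod(card)), ") exceeds enumeration cap (",
         format(cap), ")", call. = FALSE)
  }
  grid <- tibble::as_tibble(expand.grid(
    purrr::map(nodes, function(v) bn$cpts[[v]]$states) |> setNames(nodes),
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  ))
  p <- rep(1, nrow(grid))
  for (v in nodes) {
    cpt <- bn$cpts[[v]]
    key_vars <- c(cpt$parents, v)
    key <- do.call(paste, c(grid[key_vars], sep = "\r"))
    lut <- setNames(cpt$table$p, do.call(paste, c(cpt$table[key_vars], sep = "\r")))
    p <- p * lut[key]
  }
  keep <- rep(TRUE, nrow(grid))
  for (v in names(evidence)) keep <- keep & grid[[v]] == evidence[[v]]
  mass <- tapply(p[keep], grid[[query]][keep], sum)
  total <- sum(mass)
  if (!is.finite(total) || total <= 0) impossible_evidence(evidence)
  posterior_tibble(bn, query, mass / total)
}

# -- factor algebra on long tibbles (columns: variables..., p) ---------------

factor_vars <- function(f) setdiff(names(f), "p")

factor_product <- function(a, b) {
  shared <- intersect(factor_vars(a), factor_vars(b))
  if (length(shared)) {
    out <- dplyr::inner_join(a, b, by = shared, suffix = c(".x", ".y"),
                             relationship = "many-to-many")
  } else {
    out <- dplyr::cross_join(a, b, suffix = c(".x", ".y"))
  }
  out$p <- out$p.x * out$p.y
  out[c(setdiff(names(out), c("p.x", "p.y", "p")), "p")]
}

factor_marginalize <- function(f, var) {
  rest <- setdiff(factor_vars(f), var)
  if (!length(rest)) {
    return(tibble::tibble(p = sum(f$p)))
  }
  f |>
    dplyr::group_by(dplyr::across(dplyr::all_of(rest))) |>
    dplyr::summarise(p = sum(.data$p), .groups = "drop")
}

#' Posterior distribution by variable elimination
#'
#' Factor-based summation with a deterministic elimination order: at each step
#' the hidden variable with the fewest distinct neighbours across the current
#' factors is eliminated, ties broken lexicographically by variable name. The
#' contract is identical to [posterior_enumerate()] (which serves as its
#' oracle in the test-suite) without the enumeration cap.
#'
#' @inheritParams posterior_enumerate
#' @return A tibble with columns `variable`, `state`, `prob` summing to 1.
#' @export
posterior_eliminate <- function(bn, query, evidence = NULL) {
  evidence <- check_query(bn, query, evidence)
  factors <- purrr::map(bn$dag$nodes, function(v) {
    cpt <- bn$cpts[[v]]
    f <- cpt$table[c(cpt$parents, v, "p")]
    for (e in intersect(names(evidence), c(cpt$parents, v))) {
      f <- f[f[[e]] == evidence[[e]], , drop = FALSE]
      f[[e]] <- NULL
    }
    f
  })
  hidden <- setdiff(bn$dag$nodes, c(query, names(evidence)))
  while (length(hidden)) {
    # min-degree: fewest distinct co-occurring variables, lexicographic ties
    degree <- vapply(hidden, function(v) {
      nb <- unique(unlist(purrr::map(factors, function(f) {
        fv <- factor_vars(f)
        if (v %in% fv) fv else character()
      })))
      length(setdiff(nb, v))
    }, numeric(1))
    v <- sort(hidden[degree == min(degree)])[1L]
    involved <- vapply(factors, function(f) v %in% factor_vars(f), logical(1))
    merged <- Reduce(factor_product, factors[involved])
    factors <- c(factors[!involved], list(factor_marginalize(merged, v)))
    hidden <- setdiff(hidden, v)
  }
  res <- Reduce(factor_product, factors)
  states <- bn$cpts[[query]]$states
  if (!query %in% names(res)) {
    # query was fully determined by scalar factors; should not happen
    stop("internal error: query variable eliminated", call. = FALSE)
  }
  mass <- setNames(rep(0, length(states)), states)
  mass[res[[query]]] <- res$p
  total <- sum(mass)
  if (!is.finite(total) || total <= 0) impossible_evidence(evidence)
  posterior_tibble(bn, query, mass / total)
}
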