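# Bayesian-network core: DAG handling, conditional probability tables,
# maximum-likelihood / Laplace-smoothed parameter estimation, and the joint
# factorisation P(X1..Xn) = prod_i P(Xi | Parents(Xi)).

#' Construct a directed acyclic graph over named variables
#'
#' @param nodes Character vector of variable names.
#' @param edges A two-column data frame (or matrix) of directed edges
#'   `from -> to`; `NULL` for an edgeless graph.
#' @return A `bn_dag` object (list with `nodes` and an `edges` tibble).
#' @examples
#' g <- bn_dag(c("A", "B"), data.frame(from = "A", to = "B"))
#' validate_dag(g)
#' @export
bn_dag <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (is.null(edges)) {
    edges <- tibble::tibble(from = character(), to = character())
  } else {
    edges <- tibble::as_tibble(as.data.frame(edges, stringsAsFactors = FALSE))
    names(edges) <- c("from", "to")
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
  }
  structure(list(nodes = nodes, edges = edges), class = "bn_dag")
}

#' The default study graph
#'
#' Demographics drive license status (`age_band, gender -> driving_license`),
#' and `{driving_license, age_band, gender}` drive each of the six objective
#' variables (four behaviours, accident type, accident severity). This is the
#' minimal structure under which every sensitivity query of the study --
#' conditioning on license, age and gender -- is non-trivial. Behaviours do
#' not feed the accident variables by default (see
#' [default_population_spec()]).
#'
#' @param dict A variable dictionary.
#' @return A `bn_dag`.
#' @export
default_study_dag <- function(dict = default_variable_dictionary()) {
  objectives <- dictionary_variables(dict, "objective")
  edges <- dplyr::bind_rows(
    tibble::tibble(from = c("age_band", "gender"), to = "driving_license"),
    tidyr::expand_grid(from = c("driving_license", "age_band", "gender"),
                       to = objectives)
  )
  bn_dag(dict$variable, edges)
}

#' Validate a DAG
#'
#' Accepts iff the edge list is well-formed (edges reference listed nodes, no
#' duplicates) and the graph is acyclic; otherwise the diagnostic names the
#' problem, including one offending cycle.
#'
#' @param dag A `bn_dag`.
#' @return A list with `ok` (logical) and, when not ok, `message` and possibly
#'   `cycle` (the node sequence of one directed cycle).
#' @export
validate_dag <- function(dag) {
  stopifnot(inherits(dag, "bn_dag"))
  e <- dag$edges
  bad <- setdiff(unique(c(e$from, e$to)), dag$nodes)
  if (length(bad)) {
    return(list(ok = FALSE,
                message = paste0("edges reference unlisted node(s): ",
                                 paste(bad, collapse = ", "))))
  }
  if (anyDuplicated(paste(e$from, e$to, sep = "\r"))) {
    return(list(ok = FALSE, message = "duplicate edges"))
  }
  if (any(e$from == e$to)) {
    sl <- e$from[e$from == e$to][1L]
    return(list(ok = FALSE, cycle = sl,
                message = paste0("self-loop at node ", sl)))
  }
  cyc <- find_cycle(dag)
  if (!is.null(cyc)) {
    return(list(ok = FALSE, cycle = cyc,
                message = paste0("cycle: ", paste(cyc, collapse = " -> "))))
  }
  list(ok = TRUE)
}

# Depth-first search for one directed cycle; NULL if acyclic.
find_cycle <- function(dag) {
  adj <- split(dag$edges$to, factor(dag$edges$from, levels = dag$nodes))
  color <- setNames(rep(0L, length(dag$nodes)), dag$nodes) # 0 new, 1 open, 2 done
  stack <- character()
  result <- NULL
  visit <- function(v) {
    if (!is.null(result)) return()
    color[v] <<- 1L
    stack <<- c(stack, v)
    for (w in adj[[v]]) {
      if (!is.null(result)) return()
      if (color[w] == 1L) {
        i <- match(w, stack)
        result <<- c(stack[i:length(stack)], w)
        return()
      }
      if (color[w] == 0L) visit(w)
    }
    stack <<- stack[-length(stack)]
    color[v] <<- 2L
  }
  for (v in dag$nodes) if (color[v] == 0L) visit(v)
  result
}

#' Topological order of a DAG
#'
#' Kahn's algorithm with a lexicographic tie-break, so the order is
#' deterministic across platforms.
#'
#' @param dag A `bn_dag`.
#' @return Character vector of nodes, parents before children.
#' @export
topo_sort <- function(dag) {
  chk <- validate_dag(dag)
  if (!chk$ok) stop("invalid DAG: ", chk$message, call. = FALSE)
  indeg <- setNames(rep(0L, length(dag$nodes)), dag$nodes)
  tab <- table(dag$edges$to)
  indeg[names(tab)] <- as.integer(tab)
  out <- character()
  remaining <- dag$nodes
  while (length(remaining)) {
    ready <- sort(remaining[indeg[remaining] == 0L])
    v <- ready[1L]
    out <- c(out, v)
    remaining <- setdiff(remaining, v)
    kids <- dag$edges$to[dag$edges$from == v]
    indeg[kids] <- indeg[kids] - 1L
  }
  out
}

#' Parents of a node
#' @param dag A `bn_dag`.
#' @param node Node name.
#' @return Character vector of parent names (in `nodes` order).
#' @export
bn_parents <- function(dag, node) {
  p <- dag$edges$from[dag$edges$to == node]
  dag$nodes[dag$nodes %in% p]
}

#' Build a conditional probability table
#'
#' @param child Child variable name.
#' @param states Ordered child state labels.
#' @param parents Named list of parent state vectors (possibly empty), in
#'   parent order.
#' @param prob Matrix of probabilities with one row per parent configuration
#'   (configurations in [expand.grid()] order over `parents`, first parent
#'   varying fastest) and one column per child state; or a single probability
#'   vector for a root node.
#' @return A `bn_cpt` object: list with `child`, `parents`, `states`, and a
#'   long `table` tibble (parent columns, child column, `p`).
#' @examples
#' bn_cpt("B", c("0", "1"), list(A = c("0", "1")),
#'        rbind(c(0.8, 0.2), c(0.1, 0.9)))
#' @export
bn_cpt <- function(child, states, parents = list(), prob) {
  prob <- rbind(prob)
  stopifnot(ncol(prob) == length(states))
  # expand.grid varies the first parent fastest, matching the documented
  # row-order contract for `prob`.
  grid <- if (length(parents)) {
    tibble::as_tibble(expand.grid(purrr::map(parents, as.character),
                                  stringsAsFactors = FALSE,
                                  KEEP.OUT.ATTRS = FALSE))
  } else {
    tibble::tibble(.rows = 1L)
  }
  stopifnot(nrow(prob) == nrow(grid))
  tab <- grid[rep(seq_len(nrow(grid)), times = length(states)), , drop = FALSE]
  tab[[child]] <- rep(states, each = nrow(grid))
  tab$p <- as.vector(prob)
  check_cpt_rows(tab, child, names(parents))
  structure(list(child = child, parents = names(parents), states = states,
                 table = tibble::as_tibble(tab)),
            class = "bn_cpt")
}

check_cpt_rows <- function(table, child, parents, tol = 1e-9) {
  if (any(table$p < -tol)) stop("negative probability in CPT for ", child, call. = FALSE)
  sums <- if (length(parents)) {
    table |>
      dplyr::group_by(dplyr::across(dplyr::all_of(parents))) |>
      dplyr::summarise(s = sum(.data$p), .groups = "drop") |>
      dplyr::pull("s")
  } else {
    sum(table$p)
  }
  if (any(abs(sums - 1) > tol)) {
    stop("CPT row(s) for '", child, "' do not sum to 1 (max deviation ",
         format(max(abs(sums - 1))), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Assemble a Bayesian network from a DAG and CPTs
#'
#' Validates that every node has a CPT, each CPT's parent list equals the
#' node's in-neighbourhood, every parent configuration has a row, and every
#' row sums to 1 within 1e-9.
#'
#' @param dag A `bn_dag`.
#' @param cpts Named list of `bn_cpt` objects, one per node.
#' @param dictionary Optional variable dictionary; derived from the CPT state
#'   lists when omitted.
#' @return A `driver_bn` object.
#' @export
bayesian_network <- function(dag, cpts, dictionary = NULL) {
  chk <- validate_dag(dag)
  if (!chk$ok) stop("invalid DAG: ", chk$message, call. = FALSE)
  if (!setequal(names(cpts), dag$nodes)) {
    stop("CPT list must cover exactly the DAG nodes", call. = FALSE)
  }
  for (v in dag$nodes) {
    cpt <- cpts[[v]]
    stopifnot(inherits(cpt, "bn_cpt"), identical(cpt$child, v))
    if (!setequal(cpt$parents, bn_parents(dag, v))) {
      stop("CPT parents for '", v, "' do not match the DAG in-neighbourhood",
           call. = FALSE)
    }
    n_cfg <- prod(vapply(cpt$parents, function(p) length(cpts[[p]]$states), 1))
    if (nrow(cpt$table) != n_cfg * length(cpt$states)) {
      stop("CPT for '", v, "' is missing parent configurations", call. = FALSE)
    }
    check_cpt_rows(cpt$table, v, cpt$parents)
  }
  if (is.null(dictionary)) {
    dictionary <- tibble::tibble(
      variable = dag$nodes,
      role = "influential",
      states = purrr::map(dag$nodes, function(v) cpts[[v]]$states)
    )
  }
  structure(list(dag = dag, cpts = cpts[dag$nodes], dictionary = dictionary),
            class = "driver_bn")
}

#' Fit conditional probability tables to data
#'
#' Maximum-likelihood estimation with an optional Laplace pseudocount: each
#' CPT row is `(count(child = k, parents = cfg) + s) / (count(cfg) + s * K)`
#' where `K` is the number of child states. With `pseudocount = 0`, rows with
#' no supporting records are set uniform and flagged (see the `flagged`
#' element of the result). Records with an `NA` on the child or any parent are
#' excluded from that family's counts only.
#'
#' The default pseudocount of 1 reflects that the rarest stratum of interest
#' (invalid licenses, 1.51% of drivers) produces empty cells at modest sample
#' sizes.
#'
#' @param dag A `bn_dag` whose nodes are all columns of `data`.
#' @param data A driver-level tibble.
#' @param pseudocount Non-negative Laplace smoothing constant per child state.
#' @param dict Variable dictionary supplying state spaces; defaults to the
#'   study dictionary for known variables and observed values otherwise.
#' @return A fitted `driver_bn` with per-row support counts (`n_config`,
#'   `n_obs`) in each CPT table, plus `n_records`, `pseudocount`, `log_lik`
#'   and `flagged` elements.
#' @examples
#' dict <- default_variable_dictionary()
#' spec <- default_population_spec()
#' data <- generate_drivers(spec, n = 2000, seed = 1)
#' bn <- fit_bn(default_study_dag(dict), data, pseudocount = 1)
#' glance(bn)
#' @export
fit_bn <- function(dag, data, pseudocount = 1,
                   dict = NULL) {
  chk <- validate_dag(dag)
  if (!chk$ok) stop("invalid DAG: ", chk$message, call. = FALSE)
  stopifnot(pseudocount >= 0)
  missing_cols <- setdiff(dag$nodes, names(data))
  if (length(missing_cols)) {
    stop("dataset is missing variable(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) == 0 && pseudocount == 0) {
    stop("cannot fit on an empty dataset with zero pseudocount", call. = FALSE)
  }
  if (is.null(dict)) {
    base <- default_variable_dictionary()
    dict <- tibble::tibble(
      variable = dag$nodes,
      role = dplyr::coalesce(base$role[match(dag$nodes, base$variable)], "influential"),
      states = purrr::map(dag$nodes, function(v) {
        if (v %in% base$variable) variable_states(base, v)
        else sort(unique(stats::na.omit(data[[v]])))
      })
    )
  }
  states_of <- function(v) dict$states[[match(v, dict$variable)]]
  flagged <- list()
  log_lik <- 0
  cpts <- purrr::map(dag$nodes, function(v) {
    parents <- bn_parents(dag, v)
    k <- length(states_of(v))
    fam <- data[, c(parents, v), drop = FALSE]
    fam <- fam[stats::complete.cases(fam), , drop = FALSE]
    grid_vars <- c(parents, v)
    grid <- tibble::as_tibble(expand.grid(
      purrr::map(grid_vars, states_of) |> setNames(grid_vars),
      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
    ))
    counts <- fam |>
      dplyr::count(dplyr::across(dplyr::all_of(grid_vars)), name = "n_obs")
    tab <- grid |>
      dplyr::left_join(counts, by = grid_vars) |>
      dplyr::mutate(n_obs = dplyr::coalesce(.data$n_obs, 0L))
    if (length(parents)) {
      tab <- tab |>
        dplyr::group_by(dplyr::across(dplyr::all_of(parents))) |>
        dplyr::mutate(n_config = sum(.data$n_obs)) |>
        dplyr::ungroup()
    } else {
      tab$n_config <- sum(tab$n_obs)
    }
    tab$p <- (tab$n_obs + pseudocount) / (tab$n_config + pseudocount * k)
    empty <- tab$n_config == 0
    if (any(empty) && pseudocount == 0) {
      tab$p[empty] <- 1 / k
      cfg <- unique(tab[empty, parents, drop = FALSE])
      flagged[[v]] <<- cfg
    }
    log_lik <<- log_lik + sum(tab$n_obs[tab$n_obs > 0] * log(tab$p[tab$n_obs > 0]))
    structure(list(child = v, parents = parents, states = states_of(v),
                   table = tab),
              class = "bn_cpt")
  }) |> setNames(dag$nodes)
  bn <- bayesian_network(dag, cpts, dictionary = dict)
  bn$n_records <- nrow(data)
  bn$pseudocount <- pseudocount
  bn$log_lik <- log_lik
  bn$flagged <- flagged
  bn
}

#' Joint probability of a full assignment
#'
#' Evaluates the factorisation `prod_i P(Xi | Parents(Xi))` at one complete
#' state vector.
#'
#' @param bn A `driver_bn`.
#' @param assignment Named character vector with one state per network node; a
#'   partial assignment is a hard error.
#' @return A probability in `[0, 1]`.
#' @export
joint_probability <- function(bn, assignment) {
  missing <- setdiff(bn$dag$nodes, names(assignment))
  if (length(missing)) {
    stop("assignment is missing variable(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  prod(vapply(bn$dag$nodes, function(v) {
    cpt <- bn$cpts[[v]]
    tab <- cpt$table
    keep <- tab[[v]] == assignment[[v]]
    for (par in cpt$parents) keep <- keep & tab[[par]] == assignment[[par]]
    p <- tab$p[keep]
    if (length(p) != 1L) {
      stop("no CPT entry for '", v, "' at the given assignment ",
           "(unknown state label?)", call. = FALSE)
    }
    p
  }, numeric(1)))
}

#' @export
print.driver_bn <- function(x, ...) {
  cat("<driver_bn> discrete Bayesian network\n")
  cat("  nodes:", length(x$dag$nodes), " edges:", nrow(x$dag$edges), "\n")
  if (!is.null(x$n_records)) {
    cat("  fitted on", x$n_records, "records, pseudocount", x$pseudocount,
        ", logLik", format(x$log_lik), "\n")
  }
  for (v in x$dag$nodes) {
    cat("  ", v, " | ", paste(x$cpts[[v]]$parents, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a fitted network into one long CPT tibble
#'
#' @param x A `driver_bn`.
#' @param ... Unused.
#' @return A tibble with columns `variable`, `parents` (a `key=value` string,
#'   empty for roots), `state`, `p`, and support counts when fitted.
#' @method tidy driver_bn
#' @export
tidy.driver_bn <- function(x, ...) {
  purrr::map(x$dag$nodes, function(v) {
    cpt <- x$cpts[[v]]
    tab <- cpt$table
    cfg <- if (length(cpt$parents)) {
      purrr::pmap_chr(tab[cpt$parents], function(...) {
        paste(paste0(cpt$parents, "=", c(...)), collapse = ", ")
      })
    } else ""
    out <- tibble::tibble(variable = v, parents = cfg,
                          state = tab[[v]], p = tab$p)
    if ("n_obs" %in% names(tab)) {
      out$n_obs <- tab$n_obs
      out$n_config <- tab$n_config
    }
    out
  }) |> dplyr::bind_rows()
}

#' One-row summary of a fitted network
#'
#' @param x A `driver_bn`.
#' @param ... Unused.
#' @return A one-row tibble: node/edge counts, number of free parameters,
#'   records, pseudocount and training log-likelihood.
#' @method glance driver_bn
#' @export
glance.driver_bn <- function(x, ...) {
  n_par <- sum(vapply(x$cpts, function(cpt) {
    n_cfg <- nrow(cpt$table) / length(cpt$states)
    n_cfg * (length(cpt$states) - 1)
  }, numeric(1)))
  tibble::tibble(
    n_nodes = length(x$dag$nodes),
    n_edges = nrow(x$dag$edges),
    n_parameters = n_par,
    n_records = x$n_records %||% NA_integer_,
    pseudocount = x$pseudocount %||% NA_real_,
    log_lik = x$log_lik %||% NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize / deserialize a network as JSON
#'
#' Structure (nodes, edges) and embedded CPTs round-trip through a plain JSON
#' document, so fitted networks can be stored and reloaded.
#'
#' @param bn A `driver_bn`.
#' @param path File path.
#' @return `read_bn()` returns a `driver_bn`; `write_bn()` returns `path`
#'   invisibly.
#' @export
write_bn <- function(bn, path) {
  doc <- list(
    nodes = bn$dag$nodes,
    edges = bn$dag$edges,
    dictionary = purrr::pmap(bn$dictionary, function(variable, role, states) {
      list(variable = variable, role = role, states = as.character(states))
    }),
    cpts = purrr::map(bn$cpts, function(cpt) {
      list(child = cpt$child, parents = cpt$parents, states = cpt$states,
           table = cpt$table)
    })
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_bn
#' @export
read_bn <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  dag <- bn_dag(doc$nodes, doc$edges)
  dict <- parse_dictionary_doc(doc$dictionary)
  cpts <- purrr::map(doc$cpts, function(cpt) {
    structure(list(child = cpt$child,
                   parents = as.character(cpt$parents %||% character()),
                   states = as.character(cpt$states),
                   table = tibble::as_tibble(cpt$table)),
              class = "bn_cpt")
  })
  bayesian_network(dag, cpts, dictionary = dict)
}

# jsonlite may simplify the dictionary entries into a data frame or leave a
# list of records; accept both.
parse_dictionary_doc <- function(raw) {
  dict <- if (is.data.frame(raw)) {
    tibble::tibble(variable = raw$variable, role = raw$role,
                   states = purrr::map(raw$states, as.character))
  } else {
    tibble::tibble(
      variable = purrr::map_chr(raw, "variable"),
      role = purrr::map_chr(raw, "role"),
      states = purrr::map(raw, function(x) as.character(x$states))
    )
  }
  class(dict) <- c("variable_dictionary", class(dict))
  dict
}
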