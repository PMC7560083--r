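# Shared fixtures: hand-built and randomly generated small networks.

# total-variation distance between two distributions on the same support
tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# Two-node network A -> B with the classic Bayes-flip parameters:
# P(A=1)=0.5, P(B=1|A=1)=0.9, P(B=1|A=0)=0.2.
two_node_bn <- function() {
  bayesian_network(
    bn_dag(c("A", "B"), data.frame(from = "A", to = "B")),
    list(
      A = bn_cpt("A", c("0", "1"), prob = c(0.5, 0.5)),
      B = bn_cpt("B", c("0", "1"), list(A = c("0", "1")),
                 rbind(c(0.8, 0.2), c(0.1, 0.9)))
    )
  )
}

# Random categorical network with <= max_vars variables of 2-3 states each,
# random DAG (edge probability 0.4) and Dirichlet(1) CPT rows.
random_bn <- function(seed, max_vars = 6) {
  withr::with_seed(seed, {
    nv <- sample(2:max_vars, 1)
    vars <- paste0("V", seq_len(nv))
    cards <- sample(2:3, nv, replace = TRUE)
    ord <- sample(vars)
    edges <- list()
    for (i in seq_len(nv - 1)) {
      for (j in seq((i + 1), nv)) {
        if (runif(1) < 0.4) edges[[length(edges) + 1]] <- c(ord[i], ord[j])
      }
    }
    edges <- if (length(edges)) {
      do.call(rbind, edges) |> (\(m) data.frame(from = m[, 1], to = m[, 2]))()
    } else NULL
    dag <- bn_dag(vars, edges)
    states_of <- setNames(purrr::map(cards, ~as.character(seq_len(.x))), vars)
    cpts <- purrr::map(vars, function(v) {
      parents <- bn_parents(dag, v)
      n_cfg <- prod(c(1, lengths(states_of[parents])))
      raw <- matrix(stats::rgamma(n_cfg * cards[match(v, vars)], 1),
                    nrow = n_cfg)
      bn_cpt(v, states_of[[v]], states_of[parents], raw / rowSums(raw))
    }) |> setNames(vars)
    bayesian_network(dag, cpts)
  })
}

# Random query + evidence for a network: evidence on a random subset of the
# other variables, each set to a random state.
random_query <- function(bn, seed) {
  withr::with_seed(seed, {
    vars <- bn$dag$nodes
    query <- sample(vars, 1)
    others <- setdiff(vars, query)
    n_ev <- sample(0:length(others), 1)
    ev_vars <- if (n_ev) sample(others, n_ev) else character()
    ev <- vapply(ev_vars, function(v) sample(bn$cpts[[v]]$states, 1), "")
    list(query = query, evidence = ev)
  })
}
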