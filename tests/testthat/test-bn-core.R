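# DAG validation, CPT estimation and the joint factorisation.

test_that("validate_dag accepts chains and names offending cycles", {
  expect_true(validate_dag(bn_dag(c("A", "B", "C"),
                                  data.frame(from = c("A", "B"),
                                             to = c("B", "C"))))$ok)
  two_cycle <- validate_dag(bn_dag(c("A", "B"),
                                   data.frame(from = c("A", "B"),
                                              to = c("B", "A"))))
  expect_false(two_cycle$ok)
  expect_setequal(unique(two_cycle$cycle), c("A", "B"))
  expect_false(validate_dag(bn_dag("A", data.frame(from = "A", to = "A")))$ok)
  expect_false(validate_dag(bn_dag(c("A", "B"),
                                   data.frame(from = c("A", "A"),
                                              to = c("B", "B"))))$ok)
  expect_false(validate_dag(bn_dag("A", data.frame(from = "A", to = "Z")))$ok)
})

test_that("the default study graph is acyclic with parents before children", {
  dag <- default_study_dag()
  expect_true(validate_dag(dag)$ok)
  ord <- topo_sort(dag)
  expect_setequal(ord, dag$nodes)
  pos <- match(dag$nodes, ord)
  names(pos) <- dag$nodes
  for (i in seq_len(nrow(dag$edges))) {
    expect_lt(pos[dag$edges$from[i]], pos[dag$edges$to[i]])
  }
})

test_that("fit_cpts matches hand counts and normalizes every row", {
  data <- tibble::tibble(A = c("Yes", "Yes", "Yes", "No"),
                         B = c("Yes", "Yes", "Yes", "No"))
  dag <- bn_dag(c("A", "B"), data.frame(from = "A", to = "B"))
  bn <- fit_bn(dag, data, pseudocount = 0)
  tab <- bn$cpts$B$table
  expect_equal(tab$p[tab$A == "Yes" & tab$B == "Yes"], 1.0)
  expect_equal(tab$p[tab$A == "Yes" & tab$B == "No"], 0.0)
  expect_equal(bn$cpts$A$table$p[bn$cpts$A$table$A == "Yes"], 0.75)

  fitted <- fit_bn(default_study_dag(),
                   generate_drivers(default_population_spec(), 3000, seed = 5))
  for (v in fitted$dag$nodes) {
    cpt <- fitted$cpts[[v]]
    sums <- cpt$table |>
      dplyr::group_by(dplyr::across(dplyr::all_of(cpt$parents))) |>
      dplyr::summarise(s = sum(.data$p), .groups = "drop")
    expect_true(all(abs(sums$s - 1) < 1e-9))
  }
})

test_that("smoothing limits: huge pseudocounts give uniform rows, zero flags empties", {
  data <- tibble::tibble(A = c("Yes", "Yes", "No"),
                         B = c("Yes", "No", "No"))
  dag <- bn_dag(c("A", "B"), data.frame(from = "A", to = "B"))
  washed <- fit_bn(dag, data, pseudocount = 1e9)
  expect_true(all(abs(washed$cpts$B$table$p - 0.5) < 1e-6))

  # an unobserved parent configuration with zero pseudocount: uniform + flag
  dict <- tibble::tibble(variable = c("A", "B"), role = "influential",
                         states = list(c("Yes", "No", "Never"), c("Yes", "No")))
  flagged <- fit_bn(dag, data, pseudocount = 0, dict = dict)
  tab <- flagged$cpts$B$table
  expect_equal(tab$p[tab$A == "Never"], c(0.5, 0.5))
  expect_equal(flagged$flagged$B$A, "Never")

  expect_error(fit_bn(dag, data[0, ], pseudocount = 0), "empty dataset")
})

test_that("estimation is consistent: recovery error shrinks as n doubles", {
  spec <- default_population_spec()
  dag <- default_study_dag()
  err_at <- function(n) {
    data <- generate_drivers(spec, n, seed = 1)
    bn <- fit_bn(dag, data, pseudocount = 0)
    # support-weighted mean total-variation distance to the generating rows
    errs <- purrr::map_dbl(dag$nodes, function(v) {
      m <- dplyr::inner_join(bn$cpts[[v]]$table, spec$cpts[[v]]$table,
                             by = c(bn$cpts[[v]]$parents, v),
                             suffix = c("_fit", "_true"))
      sum(m$n_config * abs(m$p_fit - m$p_true) / 2) / sum(m$n_config)
    })
    mean(errs)
  }
  e <- c(err_at(25000), err_at(50000), err_at(100000))
  expect_lt(e[2], e[1])
  expect_lt(e[3], e[2])
})

test_that("joint_probability multiplies the factorization and detects errors", {
  bn <- bayesian_network(
    bn_dag(c("A", "B"), data.frame(from = "A", to = "B")),
    list(A = bn_cpt("A", c("0", "1"), prob = c(0.4, 0.6)),
         B = bn_cpt("B", c("0", "1"), list(A = c("0", "1")),
                    rbind(c(0.7, 0.3), c(0.5, 0.5))))
  )
  expect_equal(joint_probability(bn, c(A = "1", B = "1")), 0.30)
  expect_error(joint_probability(bn, c(A = "1")), "missing variable")

  zero <- bayesian_network(
    bn_dag(c("A", "B"), data.frame(from = "A", to = "B")),
    list(A = bn_cpt("A", c("0", "1"), prob = c(1, 0)),
         B = bn_cpt("B", c("0", "1"), list(A = c("0", "1")),
                    rbind(c(0.7, 0.3), c(0.5, 0.5))))
  )
  expect_equal(joint_probability(zero, c(A = "1", B = "0")), 0)
})

test_that("the joint distribution is globally normalized on random networks", {
  for (s in 1:12) {
    bn <- random_bn(s)
    grid <- expand.grid(purrr::map(bn$cpts, "states"),
                        stringsAsFactors = FALSE)
    total <- sum(vapply(seq_len(nrow(grid)), function(i) {
      joint_probability(bn, unlist(grid[i, , drop = FALSE]))
    }, numeric(1)))
    expect_equal(total, 1, tolerance = 1e-9)
  }
})

test_that("networks round-trip through JSON with fitted parameters intact", {
  data <- generate_drivers(default_population_spec(), 1000, seed = 12)
  bn <- fit_bn(default_study_dag(), data)
  path <- withr::local_tempfile(fileext = ".json")
  write_bn(bn, path)
  back <- read_bn(path)
  expect_equal(back$dag$nodes, bn$dag$nodes)
  for (v in bn$dag$nodes) {
    expect_equal(back$cpts[[v]]$table$p, bn$cpts[[v]]$table$p, tolerance = 1e-12)
  }
  q <- posterior_eliminate(back, "accident_severity", c(driving_license = "Invalid"))
  expect_equal(sum(q$prob), 1, tolerance = 1e-9)
})
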