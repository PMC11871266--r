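# DAG construction, d-separation and backdoor identification.

test_that("textbook structures d-separate as expected", {
  chain <- causal_dag(c("X", "M", "Y"), c("X -> M", "M -> Y"),
                      exposure = "X", outcome = "Y")
  expect_true(d_separated(chain, "X", "Y", "M"))
  expect_false(d_separated(chain, "X", "Y"))
  fork <- causal_dag(c("X", "Z", "Y"), c("Z -> X", "Z -> Y"),
                     exposure = "X", outcome = "Y")
  expect_true(d_separated(fork, "X", "Y", "Z"))
  expect_false(d_separated(fork, "X", "Y"))
  collider <- causal_dag(c("X", "C", "Y"), c("X -> C", "Y -> C"),
                         exposure = "X", outcome = "Y")
  expect_true(d_separated(collider, "X", "Y"))
  expect_false(d_separated(collider, "X", "Y", "C"))
  # conditioning on a collider's descendant also opens the path
  cd <- causal_dag(c("X", "C", "D", "Y"), c("X -> C", "Y -> C", "C -> D"),
                   exposure = "X", outcome = "Y")
  expect_false(d_separated(cd, "X", "Y", "D"))
})

test_that("construction rejects cycles, duplicates and bad references", {
  expect_error(
    causal_dag(c("X", "T", "Y"), c("X -> T", "T -> Y", "Y -> X"),
               exposure = "T", outcome = "Y"),
    "cycle")
  expect_error(
    causal_dag(data.frame(name = c("A", "A"), observed = TRUE,
                          role = "covariate"),
               data.frame(parent = character(0), child = character(0))),
    "duplicate")
  expect_error(
    causal_dag(c("A", "B"), "A -> Q", exposure = "A", outcome = "B"),
    "unknown node")
  expect_error(d_separated(causal_dag(c("A", "B"), "A -> B", exposure = "A",
                                      outcome = "B"), "A", "Q"),
               "unknown node")
})

test_that("backdoor sets on textbook graphs", {
  tri <- causal_dag(c("X", "T", "Y"), c("X -> T", "X -> Y", "T -> Y"),
                    exposure = "T", outcome = "Y")
  s <- backdoor_sets(tri)
  expect_length(s, 1)
  expect_equal(s[[1]]$variables, "X")
  bare <- causal_dag(c("T", "Y"), "T -> Y", exposure = "T", outcome = "Y")
  s0 <- backdoor_sets(bare)
  expect_length(s0, 1)
  expect_identical(s0[[1]]$variables, character(0))
  # unblockable latent confounding is signalled distinctly
  lat <- causal_dag(data.frame(name = c("U", "T", "Y"),
                               observed = c(FALSE, TRUE, TRUE),
                               role = c("covariate", "exposure", "outcome")),
                    c("U -> T", "U -> Y", "T -> Y"))
  expect_error(backdoor_sets(lat), class = "ventcausal_not_identifiable")
})

test_that("the packaged ventilation graph loads, is acyclic and identifiable", {
  d <- default_vent_dag()
  expect_s3_class(d, "causal_dag")
  expect_equal(dag_exposure(d), "mechanical_power")
  expect_true("vent_free_days" %in% dag_outcomes(d))
  expect_false(all(dag_nodes(d)$observed))
  s <- backdoor_sets(d, outcome = "vent_free_days")
  expect_equal(canon_sets(lapply(s, `[[`, "variables")),
               canon_sets(oracle_backdoor_sets(d, "mechanical_power",
                                               "vent_free_days",
                                               minimal_only = TRUE)))
  # every returned set passes the independent backdoor check
  for (a in s) {
    expect_true(is_valid_backdoor_set(d, a$variables,
                                      outcome = "vent_free_days"))
    expect_true(all(dag_nodes(d)$observed[match(a$variables,
                                                dag_nodes(d)$name)]))
    expect_false(any(a$variables %in%
                       dag_descendants(d, "mechanical_power")))
  }
})

test_that("graph files round-trip losslessly", {
  d <- default_vent_dag()
  p <- tempfile(fileext = ".txt")
  write_dag_file(d, p)
  d2 <- read_dag_file(p)
  expect_identical(dag_nodes(d), dag_nodes(d2))
  expect_identical(dag_edges(d), dag_edges(d2))
})

test_that("d-separation matches the path-enumeration oracle on random DAGs", {
  set.seed(2024)
  for (r in 1:60) {
    g <- random_dag(sample(4:8, 1), p_edge = 0.35, seed = 5000 + r)
    nm <- dag_nodes(g)$name
    for (q in 1:4) {
      ab <- sample(nm, 2)
      rest <- setdiff(nm, ab)
      z <- if (length(rest)) {
        rest[stats::runif(length(rest)) < 0.4]
      } else character(0)
      got <- d_separated(g, ab[1], ab[2], z)
      expect_identical(got, oracle_d_separated(g, ab[1], ab[2], z),
                       info = sprintf("rep %d query %d", r, q))
      # symmetry in (a, b)
      expect_identical(got, d_separated(g, ab[2], ab[1], z))
    }
  }
})

test_that("backdoor enumeration matches brute force on random DAGs", {
  for (r in 1:40) {
    g <- random_dag(sample(4:7, 1), p_edge = 0.35, seed = 7000 + r)
    x <- dag_exposure(g)
    y <- dag_outcomes(g)[1]
    oracle_all <- oracle_backdoor_sets(g, x, y, minimal_only = FALSE)
    got_all <- tryCatch(
      lapply(backdoor_sets(g, minimal_only = FALSE), `[[`, "variables"),
      ventcausal_not_identifiable = function(e) list())
    expect_equal(canon_sets(got_all), canon_sets(oracle_all),
                 info = paste("rep", r))
    if (length(oracle_all)) {
      got_min <- lapply(backdoor_sets(g, minimal_only = TRUE), `[[`,
                        "variables")
      expect_equal(canon_sets(got_min),
                   canon_sets(oracle_backdoor_sets(g, x, y,
                                                   minimal_only = TRUE)),
                   info = paste("rep", r))
    }
  }
})
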