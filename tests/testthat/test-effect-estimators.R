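# Backdoor OLS, cross-fitted DML, subgroup CATEs and threshold recoding.

test_that("backdoor OLS equals the normal-equations oracle to 1e-8", {
  set.seed(61)
  n <- 400
  d <- data.frame(
    t = rnorm(n), z1 = rnorm(n), z2 = rnorm(n),
    g = sample(c("a", "b", "c"), n, replace = TRUE))
  d$y <- 1 + 0.7 * d$t - 0.5 * d$z1 + 0.2 * d$z2 +
    2 * (d$g == "b") + rnorm(n)
  est <- backdoor_linear_ate(d, "t", "y", c("z1", "z2", "g"), n_boot = 50,
                             seed = 1)
  # independent route: explicit normal equations on the same design
  X <- cbind(1, d$z1, d$z2, d$g == "b", d$g == "c", d$t)
  beta <- solve(crossprod(X), crossprod(X, d$y))
  expect_lt(abs(est$point - beta[6]), 1e-8)
  expect_true(est$ci_low <= est$point && est$point <= est$ci_high)
})

test_that("backdoor OLS errors on rank deficiency and tiny samples", {
  set.seed(62)
  d <- data.frame(t = rnorm(100), z1 = rnorm(100))
  d$z2 <- 2 * d$z1                      # exact collinearity
  d$y <- rnorm(100)
  expect_error(backdoor_linear_ate(d, "t", "y", c("z1", "z2"), n_boot = 10),
               "collinear.*z2")
  expect_error(backdoor_linear_ate(d[1:4, ], "t", "y", c("z1"), n_boot = 10),
               "too few")
  # drop_aliased recovers the same treatment coefficient instead of failing
  e2 <- backdoor_linear_ate(d, "t", "y", c("z1", "z2"), n_boot = 10,
                            drop_aliased = TRUE)
  e1 <- backdoor_linear_ate(d, "t", "y", "z1", n_boot = 10)
  expect_equal(e2$point, e1$point)
})

test_that("null CI coverage is near nominal over seeded replicates", {
  # small-n replicates of a null linear model; 95% interval should cover 0
  # in at least ~90% of runs
  cover <- vapply(1:60, function(r) {
    set.seed(800 + r)
    n <- 150
    d <- data.frame(z = rnorm(n))
    d$t <- 0.8 * d$z + rnorm(n)
    d$y <- 1 + 0.5 * d$z + rnorm(n)
    e <- backdoor_linear_ate(d, "t", "y", "z", n_boot = 200, seed = r)
    e$ci_low <= 0 && 0 <= e$ci_high
  }, TRUE)
  expect_gte(mean(cover), 0.9)
})

test_that("DML is exact on degenerate inputs and errors without overlap", {
  std <- std_cohort()
  at <- std$at
  at$const_y <- 5
  for (kind in c("generic", "forest")) {
    e <- dml_ate(at, "mp_median", "const_y", std$cohort$truth$confounders,
                 learner_kind = kind, seed = 1, n_boot = 20, num_trees = 30)
    expect_identical(e$point, 0)
  }
  at$t_det <- at$apache_ii            # treatment fully explained by adjustment
  expect_error(dml_ate(at, "t_det", "vfd28", "apache_ii",
                       learner_kind = "generic", seed = 1, n_boot = 10),
               "no overlap")
})

test_that("DML with linear learners recovers the truth and approaches backdoor OLS", {
  co <- generate_cohort(sim_config(n_admissions = 10000, seed = 99,
                                   max_hours = 24))
  inc <- apply_inclusion(co$admissions, co$hourly)
  at <- analysis_table(inc$admissions, inc$hourly)
  adj <- co$truth$confounders
  lr <- backdoor_linear_ate(at, "mp_median", "vfd28", adj, n_boot = 200,
                            seed = 5)
  dm <- dml_ate(at, "mp_median", "vfd28", adj, learner_kind = "generic",
                k_folds = 5, seed = 5, n_boot = 200)
  expect_lt(abs(dm$point - (-0.15)), 2 * dm$se)
  joint_se <- sqrt(lr$se^2 + dm$se^2)
  expect_lt(abs(dm$point - lr$point), 3 * joint_se)
})

test_that("DML is deterministic given the seed", {
  std <- std_cohort()
  at <- std$at[1:800, ]
  a <- dml_ate(at, "mp_median", "vfd28", std$cohort$truth$confounders,
               learner_kind = "forest", seed = 42, n_boot = 50,
               num_trees = 50)
  b <- dml_ate(at, "mp_median", "vfd28", std$cohort$truth$confounders,
               learner_kind = "forest", seed = 42, n_boot = 50,
               num_trees = 50)
  expect_identical(a$point, b$point)
  expect_identical(a$ci_low, b$ci_low)
})

test_that("a single-level grouping reproduces the ATE call bit for bit", {
  std <- std_cohort()
  at <- std$at
  at$one <- "all"
  adj <- std$cohort$truth$confounders
  ate <- backdoor_linear_ate(at, "mp_median", "vfd28", adj, n_boot = 100,
                             seed = 9)
  cs <- cate_by_subgroup(at, "one", "mp_median", "vfd28", adj,
                         min_n = 10, seed = 9, n_boot = 100)
  expect_length(cs, 1)
  expect_identical(cs[[1]]$point, ate$point)
  expect_identical(cs[[1]]$ci_low, ate$ci_low)
  expect_identical(cs[[1]]$ci_high, ate$ci_high)
})

test_that("undersized subgroups are suppressed, not estimated", {
  std <- std_cohort()
  at <- std$at
  at$grp <- ifelse(seq_len(nrow(at)) <= 30, "tiny", "big")
  cs <- cate_by_subgroup(at, "grp", "mp_median", "vfd28",
                         std$cohort$truth$confounders, min_n = 50,
                         seed = 1, n_boot = 50)
  tiny <- Filter(function(e) e$subgroup == "tiny", cs)[[1]]
  expect_true(tiny$suppressed)
  expect_true(is.na(tiny$point))
  expect_equal(tiny$n, 30)
  big <- Filter(function(e) e$subgroup == "big", cs)[[1]]
  expect_false(big$suppressed)
  expect_error(cate_by_subgroup(at, "nope", "mp_median", "vfd28",
                                std$cohort$truth$confounders),
               "unknown grouping")
})

test_that("threshold recoding recovers a configured step effect", {
  co <- generate_cohort(sim_config(n_admissions = 4000, seed = 21,
                                   max_hours = 24, true_ate_vfd = 0,
                                   true_vfd_step = -2))
  at <- analysis_table(co$admissions, co$hourly)
  e <- binary_effect_at_threshold(at, 17, "mp_median", "vfd28",
                                  co$truth$confounders, n_boot = 200,
                                  seed = 2)
  expect_lt(abs(e$point - (-2)), 2 * e$se)
  expect_equal(e$treatment_coding, "binary_threshold(17)")
})

test_that("threshold recoding is antisymmetric and flags degenerate thresholds", {
  std <- std_cohort()
  at <- std$at
  adj <- std$cohort$truth$confounders
  e <- binary_effect_at_threshold(at, 17, "mp_median", "vfd28", adj,
                                  n_boot = 20, seed = 3)
  flipped <- at
  flipped$.treated <- 1 - as.numeric(at$mp_median > 17)
  ef <- backdoor_linear_ate(flipped, ".treated", "vfd28", adj, n_boot = 20,
                            seed = 3)
  expect_equal(ef$point, -e$point, tolerance = 1e-12)
  expect_error(
    binary_effect_at_threshold(at, min(at$mp_median) - 1, "mp_median",
                               "vfd28", adj),
    class = "ventcausal_degenerate_threshold")
})

test_that("permuting treatment within adjustment strata nulls every estimator", {
  std <- std_cohort()
  at <- std$at
  set.seed(77)
  # permute within admission-type strata (a coarse adjustment stratum)
  for (g in unique(at$admission_type)) {
    ix <- which(at$admission_type == g)
    at$mp_median[ix] <- sample(at$mp_median[ix])
  }
  adj <- std$cohort$truth$confounders
  lr <- backdoor_linear_ate(at, "mp_median", "vfd28", adj, n_boot = 100,
                            seed = 6)
  expect_lt(abs(lr$point), 2 * lr$se)
  dm <- dml_ate(at, "mp_median", "vfd28", adj, learner_kind = "generic",
                seed = 6, n_boot = 50)
  expect_lt(abs(dm$point), 2 * dm$se)
})

test_that("estimates export as a tidy, stable CSV", {
  std <- std_cohort()
  e <- backdoor_linear_ate(std$at, "mp_median", "vfd28",
                           std$cohort$truth$confounders, n_boot = 20,
                           seed = 1)
  p <- tempfile(fileext = ".csv")
  write_estimates_csv(list(e), p)
  x <- read.csv(p, stringsAsFactors = FALSE)
  expect_equal(names(x),
               c("estimand", "estimator_tag", "treatment_var",
                 "treatment_coding", "outcome_var", "subgroup", "point",
                 "ci_low", "ci_high", "se", "n", "adjustment_set",
                 "suppressed"))
  expect_equal(x$point, e$point, tolerance = 1e-8)
})
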