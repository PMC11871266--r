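# Synthetic cohort generator: structure, determinism, calibration and the
# recoverability of its configured causal truth.

test_that("sim_config validates fields and names the offender", {
  expect_error(sim_config(n_admissions = 0), "n_admissions")
  expect_error(sim_config(frac_medical = 1.2), "frac_medical")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(max_hours = 0), "max_hours")
  bad_mix <- default_diagnosis_mix()
  bad_mix$medical <- c(shock = 0.7, infection = 0.2)   # sums to 0.9
  expect_error(sim_config(diagnosis_mix = bad_mix), "diagnosis_mix")
  nsd <- default_noise_sd(); nsd["pf"] <- -1
  expect_error(sim_config(noise_sd_map = nsd), "noise_sd_map")
  expect_error(sim_config(true_cate_map = c(banana = -0.1)), "true_cate_map")
})

test_that("equal config and seed give byte-identical cohorts", {
  cfg <- sim_config(n_admissions = 200, seed = 5, max_hours = 10)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(sim_config(n_admissions = 200, seed = 6, max_hours = 10))
  expect_false(identical(a$hourly, c2$hourly))
})

test_that("cohort structure invariants hold", {
  co <- std_cohort()$cohort
  expect_true(all(co$hourly$admission_id %in% co$admissions$admission_id))
  sp <- split(co$hourly$hour, co$hourly$admission_id)
  expect_true(all(vapply(sp, function(h) identical(h, seq_along(h) - 1L), TRUE)))
  n_hours <- vapply(sp, length, 1L)
  cap <- pmin(co$config$max_hours,
              ceiling(co$admissions$intubation_duration_hours))
  names(cap) <- co$admissions$admission_id
  expect_equal(unname(n_hours[names(cap)]), as.integer(unname(cap)))
  expect_true(all(co$admissions$vfd28 >= 0 & co$admissions$vfd28 <= 28))
  h <- co$hourly
  expect_true(all(h$p_peak >= h$peep))
  expect_true(all(h$fio2 >= 0.21 & h$fio2 <= 1))
  expect_true(all(h$vt > 0))
})

test_that("medical fraction lands inside analytic binomial bounds", {
  co <- generate_cohort(sim_config(n_admissions = 1000, frac_medical = 0.42,
                                   seed = 7, max_hours = 4))
  n_med <- sum(co$admissions$admission_type == "medical")
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.42)
  expect_gte(n_med, bounds[1])
  expect_lte(n_med, bounds[2])
})

test_that("generated ventilator settings are loosely calibrated to ICU scale", {
  at <- std_cohort()$at
  expect_gt(mean(at$mp_median), 12)
  expect_lt(mean(at$mp_median), 24)
  m <- tapply(at$mp_median, at$admission_type, mean)
  expect_gt(m[["medical"]], m[["surgical"]])  # sicker arm gets more power
})

test_that("the adjusted regression recovers the configured ATE and a null ATE", {
  std <- std_cohort()
  est <- backdoor_linear_ate(std$at, "mp_median", "vfd28",
                             std$cohort$truth$confounders, n_boot = 200,
                             seed = 1)
  expect_lt(abs(est$point - (-0.15)), 2 * est$se)
  co0 <- generate_cohort(sim_config(n_admissions = 5000, true_ate_vfd = 0,
                                    seed = 88, max_hours = 24))
  inc0 <- apply_inclusion(co0$admissions, co0$hourly)
  at0 <- analysis_table(inc0$admissions, inc0$hourly)
  est0 <- backdoor_linear_ate(at0, "mp_median", "vfd28",
                              co0$truth$confounders, n_boot = 200, seed = 2)
  expect_lt(abs(est0$point), 2 * est0$se)
})

test_that("permuting MP across admissions breaks the causal link", {
  std <- std_cohort()
  at <- std$at
  set.seed(123)
  at$mp_median <- sample(at$mp_median)
  est <- backdoor_linear_ate(at, "mp_median", "vfd28",
                             std$cohort$truth$confounders, n_boot = 200,
                             seed = 3)
  expect_lt(abs(est$point), 2 * est$se)
})

test_that("cohort-specific effects follow the configured CATE map", {
  co <- generate_cohort(sim_config(
    n_admissions = 12000, seed = 55, max_hours = 24,
    true_cate_map = c(medical = -0.17, surgical = -0.07)))
  at <- analysis_table(co$admissions, co$hourly)
  cs <- cate_by_subgroup(at, "admission_type", "mp_median", "vfd28",
                         co$truth$confounders, n_boot = 200, seed = 4)
  truth <- c(medical = -0.17, surgical = -0.07)
  for (e in cs) {
    expect_lt(abs(e$point - truth[[e$subgroup]]), 2 * e$se)
  }
})

test_that("missingness injection is seeded, proportional and identity at rate 0", {
  co <- generate_cohort(sim_config(n_admissions = 250, seed = 10,
                                   max_hours = 10))
  expect_identical(inject_missingness(co, 0, 1), co)
  m1 <- inject_missingness(co, 0.1, 99)
  m2 <- inject_missingness(co, 0.1, 99)
  expect_identical(m1, m2)
  expect_identical(m1$truth, co$truth)
  n_slots <- 4 * nrow(co$hourly)
  n_missing <- sum(is.na(m1$hourly[c("vt", "rr", "peep", "p_peak")]))
  bounds <- qbinom(c(0.005, 0.995), n_slots, 0.1)
  expect_gte(n_missing, bounds[1])
  expect_lte(n_missing, bounds[2])
  expect_error(inject_missingness(co, 1, 1), "rate")
})

test_that("heavy missingness plus inclusion drops exactly the under-observed admissions", {
  co <- generate_cohort(sim_config(n_admissions = 120, seed = 20,
                                   max_hours = 6, spontaneous_rate = 0))
  m <- inject_missingness(co, 0.5, 7)
  inc <- apply_inclusion(m$admissions, m$hourly)
  h <- m$hourly
  complete <- !is.na(h$vt) & !is.na(h$rr) & !is.na(h$peep) & !is.na(h$p_peak)
  n_complete <- tapply(complete, h$admission_id, sum)
  should_keep <- names(n_complete)[n_complete >= 2]
  expect_setequal(inc$admissions$admission_id, should_keep)
})
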