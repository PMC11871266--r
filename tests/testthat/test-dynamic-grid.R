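# Hour x MP-threshold effect surface and the optimal-MP path.

test_that("grid dimensions, masking shapes and constructor invariants", {
  g <- fit_cate_grid(grid_cohort()$inc$hourly, grid_cohort()$inc$admissions,
                     hours = 0:20, thresholds = seq(0, 40, 2),
                     min_cell_n = 40, seed = 1)
  expect_s3_class(g, "cate_grid")
  expect_equal(dim(g$estimates), c(21, 21))
  expect_equal(dim(g$mask), dim(g$estimates))
  expect_true(all(is.na(g$estimates[g$mask])))
  expect_true(all(g$n_matrix[!g$mask] >= 2 * 40))
  expect_error(cate_grid(0:3, c(5, 2), matrix(0, 4, 2)), "increasing")
  expect_error(cate_grid(0:3, 1:2, matrix(0, 3, 2)), "hours x thresholds")
})

test_that("a cohort too small for any cell yields a fully masked grid, not an error", {
  inc <- grid_cohort()$inc
  few <- inc$admissions[1:10, ]
  g <- fit_cate_grid(inc$hourly, few, hours = 0:5, thresholds = 0:5,
                     min_cell_n = 50, seed = 1)
  expect_true(all(g$mask))
  expect_error(
    fit_cate_grid(inc$hourly, inc$admissions[0, ], hours = 0:5,
                  thresholds = 0:5),
    "no admissions")
})

test_that("cell estimates are identical alone or inside the full grid", {
  inc <- grid_cohort()$inc
  full <- fit_cate_grid(inc$hourly, inc$admissions, hours = 0:10,
                        thresholds = seq(10, 30, 5), min_cell_n = 40,
                        seed = 1)
  single <- fit_cate_grid(inc$hourly, inc$admissions, hours = 6,
                          thresholds = 20, min_cell_n = 40, seed = 1,
                          min_intubation_hours = 11)
  i <- match(6, full$hours); j <- match(20, full$thresholds)
  expect_identical(single$estimates[1, 1], full$estimates[i, j])
  expect_identical(single$se[1, 1], full$se[i, j])
})

test_that("the fitted surface separates above- from below-threshold cells", {
  inc <- grid_cohort()$inc
  g <- fit_cate_grid(inc$hourly, inc$admissions, hours = 0:20,
                     thresholds = 0:40, min_cell_n = 40, seed = 1)
  above <- g$thresholds >= 17
  m_above <- mean(g$estimates[, above], na.rm = TRUE)
  m_below <- mean(g$estimates[, !above], na.rm = TRUE)
  pooled <- sqrt(
    mean(g$se[, above]^2, na.rm = TRUE) / sum(!is.na(g$estimates[, above])) +
    mean(g$se[, !above]^2, na.rm = TRUE) / sum(!is.na(g$estimates[, !above])))
  expect_lt(m_above, 0)
  expect_gt((m_below - m_above) / pooled, 2)
})

test_that("a null-effect cohort keeps approximate type-I control on the surface", {
  co <- generate_cohort(sim_config(n_admissions = 1200, seed = 78,
                                   max_hours = 30, true_pf_effect = 0))
  inc <- apply_inclusion(co$admissions, co$hourly)
  g <- fit_cate_grid(inc$hourly, inc$admissions, hours = 0:20,
                     thresholds = 0:40, min_cell_n = 40, seed = 1)
  z <- abs(g$estimates / g$se)
  expect_lte(mean(z[!g$mask] > 2), 0.10)
})

test_that("more admissions never mask more cells (same underlying draw)", {
  inc <- grid_cohort()$inc
  half_ids <- inc$admissions$admission_id[
    seq_len(nrow(inc$admissions) %/% 2)]
  half <- inc$admissions[inc$admissions$admission_id %in% half_ids, ]
  gh <- fit_cate_grid(inc$hourly, half, hours = 0:15, thresholds = 0:40,
                      min_cell_n = 30, seed = 1)
  gf <- fit_cate_grid(inc$hourly, inc$admissions, hours = 0:15,
                      thresholds = 0:40, min_cell_n = 30, seed = 1)
  expect_lte(sum(gf$mask), sum(gh$mask))
})

test_that("optimal path takes per-hour argmins with low-MP tie-breaks", {
  est <- matrix(NA_real_, 2, 4)
  est[1, ] <- c(0.5, -0.2, -0.9, -0.1)
  est[2, ] <- c(0.3, -0.7, 0.1, -0.7)
  g <- cate_grid(c(3L, 4L), c(10, 20, 30, 40), est,
                 mask = matrix(FALSE, 2, 4), estimator_tag = "synthetic")
  p <- optimal_threshold_path(g)
  expect_equal(unname(p), c(30, 20))   # argmin; tie at hour 4 -> lowest MP
})

test_that("optimal path equals the per-column scan oracle on random grids", {
  for (r in 1:100) {
    g <- random_grid(sample(5:41, 1), sample(5:41, 1),
                     p_masked = runif(1, 0, 0.4), seed = 9000 + r)
    expect_equal(unname(optimal_threshold_path(g)), oracle_argmin_path(g),
                 info = paste("rep", r))
  }
  # a fully masked hour is undefined, not an error
  g <- random_grid(4, 4, p_masked = 0, seed = 1)
  g$mask[2, ] <- TRUE
  g$estimates[2, ] <- NA_real_
  p <- optimal_threshold_path(g)
  expect_true(is.na(p[2]) && !anyNA(p[-2]))
})

test_that("grid exports round-trip losslessly", {
  inc <- grid_cohort()$inc
  g <- fit_cate_grid(inc$hourly, inc$admissions, hours = 0:8,
                     thresholds = seq(5, 35, 5), min_cell_n = 40, seed = 3)
  p <- tempfile(fileext = ".csv")
  write_grid_csv(g, p)
  g2 <- read_grid_csv(p)
  expect_equal(g2$estimates, g$estimates, tolerance = 1e-9)
  expect_identical(g2$mask, g$mask)
  expect_equal(g2$n_matrix, g$n_matrix)
  expect_identical(g2$cohort, g$cohort)
  pm <- tempfile(fileext = ".csv")
  write_grid_matrix(g, pm)
  m <- as.matrix(read.csv(pm, row.names = 1))
  expect_equal(unname(m), unname(g$estimates), tolerance = 1e-9)
})
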