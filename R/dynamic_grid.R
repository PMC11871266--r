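# Hour x MP-threshold CATE surface: for every post-intubation hour h and
# threshold theta, the effect of 1{MP at h > theta} on the next-interval P/F,
# adjusted for the previous hour's observed covariates plus admission-level
# covariates. One model per cell; cells below the minimum per-arm size are
# masked, never zero-filled.

#' Construct a CATE grid object
#'
#' Low-level constructor (also used to build synthetic surfaces in tests and
#' simulations). Shapes must agree: `estimates`, `se`, `mask` and `n_matrix`
#' are `length(hours) x length(thresholds)` matrices.
#'
#' @param hours Ordered integer vector of hours since intubation.
#' @param thresholds Ordered numeric vector of MP thresholds (J/min).
#' @param estimates Matrix of effect points (P/F units); masked cells `NA`.
#' @param se Matrix of standard errors (optional, `NA` allowed).
#' @param mask Logical matrix, `TRUE` = suppressed.
#' @param n_matrix Integer matrix of per-cell admission counts.
#' @param cohort Cohort label.
#' @param estimator_tag Estimator used per cell.
#' @param seed Seed recorded for provenance.
#' @return Object of class `cate_grid`.
#' @export
cate_grid <- function(hours, thresholds, estimates, se = NULL, mask = NULL,
                      n_matrix = NULL, cohort = "all",
                      estimator_tag = "backdoor_lr", seed = NA_integer_) {
  hours <- as.integer(hours)
  if (is.unsorted(hours, strictly = TRUE) ||
      is.unsorted(thresholds, strictly = TRUE)) {
    stop("cate_grid: hours and thresholds must be strictly increasing",
         call. = FALSE)
  }
  dims <- c(length(hours), length(thresholds))
  if (!all(dim(estimates) == dims)) {
    stop("cate_grid: estimates must be hours x thresholds", call. = FALSE)
  }
  if (is.null(mask)) mask <- is.na(estimates)
  if (is.null(se)) se <- matrix(NA_real_, dims[1L], dims[2L])
  if (is.null(n_matrix)) n_matrix <- matrix(NA_integer_, dims[1L], dims[2L])
  for (m in list(se, mask, n_matrix)) {
    if (!all(dim(m) == dims)) stop("cate_grid: shape mismatch", call. = FALSE)
  }
  estimates[mask] <- NA_real_  # masked cells carry no estimate
  structure(list(cohort = cohort, hours = hours, thresholds = thresholds,
                 estimates = estimates, se = se, mask = mask,
                 n_matrix = n_matrix, estimator_tag = estimator_tag,
                 seed = seed),
            class = "cate_grid")
}

#' @export
print.cate_grid <- function(x, ...) {
  cat(sprintf("cate_grid [%s]: %d hours x %d thresholds, %d/%d cells masked\n",
              x$cohort, length(x$hours), length(x$thresholds), sum(x$mask),
              length(x$mask)))
  invisible(x)
}

#' Fit the hour x MP-threshold effect surface
#'
#' For each cell `(h, theta)` the treatment is `1{MP at hour h > theta}`, the
#' outcome is the P/F ratio at `h + outcome_lead`, and the adjustment set is
#' the previous hour's (clamped at hour 0) observed hourly covariates plus
#' the admission covariates. Each cell is an independent least-squares model
#' (treatment coefficient by QR with analytic standard errors; ~1700 models
#' per cohort make per-cell bootstrapping impractical, and the admission-level
#' estimators remain available for any single threshold of interest). Cells
#' with fewer than `min_cell_n` admissions in either arm are masked.
#'
#' @param hourly Hourly table (internal units, inclusion-filtered).
#' @param admissions Admission table.
#' @param cohort Either `"all"`, or `list(column =, value =)` selecting a
#'   subgroup (e.g. `list(column = "admission_type", value = "medical")`).
#' @param hours,thresholds Grid axes (defaults 0-40 h, 0-40 J/min step 1).
#' @param outcome_lead Hours ahead for the outcome (default 1).
#' @param hourly_covariates Hourly columns adjusted for at `h - 1`.
#' @param admission_covariates Admission columns adjusted for.
#' @param min_cell_n Minimum admissions per arm per cell (default 50).
#' @param min_intubation_hours Horizon filter: admissions must be intubated
#'   at least this long (default `max(hours) + outcome_lead`).
#' @param seed Recorded on the grid (cell fits are deterministic).
#' @return A [cate_grid()].
#' @export
fit_cate_grid <- function(hourly, admissions, cohort = "all",
                          hours = 0:40, thresholds = 0:40,
                          outcome_lead = 1,
                          hourly_covariates = c("wbc", "temperature", "ph",
                                                "map", "paco2", "fio2"),
                          admission_covariates = c("age_band",
                                                   "admission_type",
                                                   "diagnosis_group",
                                                   "apache_ii"),
                          min_cell_n = 50,
                          min_intubation_hours = max(hours) + outcome_lead,
                          seed = 1L) {
  adm <- admissions
  label <- "all"
  if (is.list(cohort)) {
    adm <- adm[adm[[cohort$column]] == cohort$value, , drop = FALSE]
    label <- paste0(cohort$column, "=", cohort$value)
  }
  adm <- adm[adm$intubation_duration_hours >= min_intubation_hours, ,
             drop = FALSE]
  if (nrow(adm) == 0L) {
    stop("fit_cate_grid: no admissions pass the horizon/cohort filter",
         call. = FALSE)
  }
  ids <- adm$admission_id
  n <- length(ids)
  h_all <- min(c(hours - 1L, 0L)):(max(hours) + outcome_lead)
  hh <- hourly[hourly$admission_id %in% ids & hourly$hour %in% h_all, ,
               drop = FALSE]
  row_i <- match(hh$admission_id, ids)
  col_i <- match(hh$hour, h_all)
  grab <- function(v) {
    m <- matrix(NA_real_, n, length(h_all))
    m[cbind(row_i, col_i)] <- v
    m
  }
  ok_mp <- !is.na(hh$vt) & !is.na(hh$rr) & !is.na(hh$peep) & !is.na(hh$p_peak)
  mp_vals <- rep(NA_real_, nrow(hh))
  mp_vals[ok_mp] <- mechanical_power(hh$vt[ok_mp], hh$rr[ok_mp],
                                     hh$peep[ok_mp], hh$p_peak[ok_mp])
  mp_mat <- grab(mp_vals)
  pf_mat <- grab(ifelse(!is.na(hh$pao2) & !is.na(hh$fio2),
                        hh$pao2 / hh$fio2, NA_real_))
  cov_mats <- lapply(hourly_covariates, function(v) grab(hh[[v]]))
  names(cov_mats) <- hourly_covariates

  adm_vars <- drop_constant_vars(adm, intersect(admission_covariates,
                                                names(adm)))
  X_adm <- adjustment_design(adm, adm_vars)

  nh <- length(hours)
  nt <- length(thresholds)
  est <- matrix(NA_real_, nh, nt)
  se <- matrix(NA_real_, nh, nt)
  nmat <- matrix(0L, nh, nt)
  mask <- matrix(TRUE, nh, nt)

  for (i in seq_len(nh)) {
    h <- hours[i]
    hc <- max(h - 1L, min(h_all))           # covariate hour, clamped at 0
    ci_h <- match(h, h_all)
    ci_cov <- match(hc, h_all)
    ci_out <- match(h + outcome_lead, h_all)
    tvec <- mp_mat[, ci_h]
    yvec <- pf_mat[, ci_out]
    C <- do.call(cbind, lapply(cov_mats, function(m) m[, ci_cov]))
    rows <- !is.na(tvec) & !is.na(yvec) & stats::complete.cases(C)
    if (sum(rows) < 2L * min_cell_n) next
    X <- cbind(X_adm[rows, , drop = FALSE], C[rows, , drop = FALSE])
    # drop collinear columns once per hour
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
      qx <- qr(X)
    }
    y <- yvec[rows]
    ry <- qr.resid(qx, y)
    mp_h <- tvec[rows]
    n_cell <- length(y)
    p <- ncol(X)
    for (j in seq_len(nt)) {
      tr <- as.numeric(mp_h > thresholds[j])
      n1 <- sum(tr)
      n0 <- n_cell - n1
      nmat[i, j] <- n_cell
      if (n1 < min_cell_n || n0 < min_cell_n) next
      rt <- qr.resid(qx, tr)
      s_tt <- sum(rt^2)
      if (s_tt < 1e-10) next
      theta <- sum(rt * ry) / s_tt
      rss <- sum(ry^2) - theta^2 * s_tt
      dfree <- n_cell - p - 1L
      if (dfree < 1L) next
      est[i, j] <- theta
      se[i, j] <- sqrt(max(rss, 0) / dfree / s_tt)
      mask[i, j] <- FALSE
    }
  }
  cate_grid(hours, thresholds, est, se, mask, nmat, cohort = label,
            estimator_tag = "backdoor_lr", seed = as.integer(seed))
}

#' Per-hour optimal MP path over a fitted grid
#'
#' For each hour, the threshold minimising the estimated effect among
#' unmasked cells (sign convention: lower effect on the surface, less
#' ventilator-induced injury). Ties are broken toward the LOWEST MP
#' (least-energy principle). Hours with every cell masked are `NA`.
#'
#' @param grid A [cate_grid()].
#' @return Numeric vector (length `length(grid$hours)`) of MP values on the
#'   grid's threshold axis, named by hour.
#' @export
optimal_threshold_path <- function(grid) {
  stopifnot(inherits(grid, "cate_grid"))
  out <- vapply(seq_along(grid$hours), function(i) {
    row <- grid$estimates[i, ]
    if (all(is.na(row))) return(NA_real_)
    grid$thresholds[which.min(row)]  # first minimum = lowest threshold
  }, numeric(1))
  stats::setNames(out, grid$hours)
}

#' Export / import a CATE grid
#'
#' `write_grid_csv()` writes the long form (cohort, hour, threshold,
#' estimate, ci_low, ci_high, n, masked) with provenance in `#key=value`
#' header comments; masked cells carry empty estimate fields and
#' `masked=TRUE` (a distinct sentinel, never silent zeros).
#' `read_grid_csv()` reconstructs the `cate_grid` losslessly.
#' `write_grid_matrix()` writes the dense estimate matrix (rows = hours,
#' columns = thresholds, masked cells `NA`).
#'
#' @param grid A [cate_grid()].
#' @param path Output path.
#' @export
write_grid_csv <- function(grid, path) {
  long <- expand.grid(hour = grid$hours, threshold = grid$thresholds,
                      KEEP.OUT.ATTRS = FALSE)
  i <- match(long$hour, grid$hours)
  j <- match(long$threshold, grid$thresholds)
  ij <- cbind(i, j)
  long$cohort <- grid$cohort
  long$estimate <- grid$estimates[ij]
  long$ci_low <- grid$estimates[ij] - 1.96 * grid$se[ij]
  long$ci_high <- grid$estimates[ij] + 1.96 * grid$se[ij]
  long$se <- grid$se[ij]
  long$n <- grid$n_matrix[ij]
  long$masked <- grid$mask[ij]
  long <- long[order(long$hour, long$threshold),
               c("cohort", "hour", "threshold", "estimate", "ci_low",
                 "ci_high", "se", "n", "masked")]
  hdr <- c(sprintf("#cohort=%s", grid$cohort),
           sprintf("#estimator_tag=%s", grid$estimator_tag),
           sprintf("#seed=%d", grid$seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(format(long, digits = 12, trim = TRUE,
                          scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  kv <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  x <- utils::read.csv(text = lines[!startsWith(lines, "#")],
                       stringsAsFactors = FALSE)
  hours <- sort(unique(x$hour))
  thresholds <- sort(unique(x$threshold))
  ij <- cbind(match(x$hour, hours), match(x$threshold, thresholds))
  mk <- function(v, default) {
    m <- matrix(default, length(hours), length(thresholds))
    m[ij] <- v
    m
  }
  cate_grid(hours, thresholds, mk(x$estimate, NA_real_),
            mk(x$se, NA_real_),
            mk(as.logical(x$masked), TRUE), mk(as.integer(x$n), 0L),
            cohort = meta[["cohort"]], estimator_tag = meta[["estimator_tag"]],
            seed = as.integer(meta[["seed"]]))
}

#' @rdname write_grid_csv
#' @export
write_grid_matrix <- function(grid, path) {
  m <- grid$estimates
  dimnames(m) <- list(paste0("hour_", grid$hours),
                      paste0("mp_", grid$thresholds))
  utils::write.csv(m, path, na = "NA")
  invisible(path)
}
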