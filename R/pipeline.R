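# End-to-end orchestration: inclusion/exclusion filtering, Table-1-style
# descriptives, the full estimation battery, optional grid/trajectory stages,
# reproducible report output, and the external-schema mapping stub.

#' Apply the study inclusion and exclusion filters
#'
#' Filters, in order: (1) adults only, when a raw `age_years` column is
#' present (the closed age-band vocabulary otherwise implies eligibility);
#' (2) admissions with fewer than `min_complete_hours` hours carrying all
#' four MP inputs are excluded (incomplete data for MP); (3) hours flagged
#' spontaneous-mode are dropped, and admissions left with fewer than
#' `min_complete_hours` qualifying hours are excluded. Per-step counts are
#' returned; they are non-increasing by construction.
#'
#' @param admissions Admission table.
#' @param hourly Hourly table (internal units).
#' @param min_complete_hours Minimum complete MP hours to retain an
#'   admission (default 2).
#' @return List: `admissions`, `hourly` (spontaneous hours removed, only
#'   retained admissions), `counts` (named integer vector of admissions
#'   remaining after each step).
#' @export
apply_inclusion <- function(admissions, hourly, min_complete_hours = 2) {
  need_h <- c("admission_id", "hour", "vt", "rr", "peep", "p_peak",
              "mode_spontaneous")
  miss <- setdiff(need_h, names(hourly))
  if (length(miss)) {
    stop("apply_inclusion: hourly table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"admission_id" %in% names(admissions)) {
    stop("apply_inclusion: admissions table missing column admission_id",
         call. = FALSE)
  }
  counts <- c(initial = nrow(admissions))
  adm <- admissions
  if ("age_years" %in% names(adm)) {
    adm <- adm[!is.na(adm$age_years) & adm$age_years >= 18, , drop = FALSE]
    counts <- c(counts, adult = nrow(adm))
  }
  h <- hourly[hourly$admission_id %in% adm$admission_id, , drop = FALSE]
  complete <- !is.na(h$vt) & !is.na(h$rr) & !is.na(h$peep) & !is.na(h$p_peak)
  n_complete <- table(factor(h$admission_id[complete],
                             levels = adm$admission_id))
  adm <- adm[n_complete[adm$admission_id] >= min_complete_hours, ,
             drop = FALSE]
  counts <- c(counts, mp_complete = nrow(adm))
  h <- h[h$admission_id %in% adm$admission_id &
           !(h$mode_spontaneous %in% 1), , drop = FALSE]
  complete <- !is.na(h$vt) & !is.na(h$rr) & !is.na(h$peep) & !is.na(h$p_peak)
  n_complete <- table(factor(h$admission_id[complete],
                             levels = adm$admission_id))
  adm <- adm[n_complete[adm$admission_id] >= min_complete_hours, ,
             drop = FALSE]
  counts <- c(counts, active_mode = nrow(adm))
  h <- h[h$admission_id %in% adm$admission_id, , drop = FALSE]
  rownames(adm) <- rownames(h) <- NULL
  list(admissions = adm, hourly = h, counts = counts)
}

table_one_variables <- function() {
  list(
    continuous = c("map_mean" = "Mean arterial pressure",
                   "pao2_mean" = "PaO2",
                   "spo2_mean" = "SpO2",
                   "fio2_mean" = "FiO2 (%)",
                   "temperature_mean" = "Temperature",
                   "apache_ii" = "APACHE II",
                   "mp_mean" = "Mechanical power",
                   "rr_mean" = "Respiratory rate",
                   "vt_ml_mean" = "Tidal volume (mL)",
                   "minute_ventilation_mean" = "Minute ventilation",
                   "peep_mean" = "PEEP",
                   "p_peak_mean" = "Peak pressure",
                   "driving_pressure_mean" = "Driving pressure"),
    skewed = c("intubation_duration_hours" = "Intubation duration (h)"),
    categorical = c("age_band" = "Age band")
  )
}

#' Descriptive cohort table with medical vs surgical comparisons
#'
#' Mean (SD) with Student's t-test for approximately normal variables,
#' median (IQR) with the Mann-Whitney U test for skewed ones, and n (%)
#' with the chi-square test for categoricals, computed over the first
#' `window_hours` of each admission. p-values are descriptive; no
#' multiplicity correction is applied.
#'
#' @param admissions,hourly Inclusion-filtered tables.
#' @param window_hours Descriptive window (default 24).
#' @return Data frame: `variable`, `type`, `level`, `overall`, `medical`,
#'   `surgical`, `test`, `p_value` (numeric, `NA` with a reason in `test`
#'   when a group is too small).
#' @export
table_one <- function(admissions, hourly, window_hours = 24) {
  if (nrow(admissions) == 0L) stop("table_one: empty cohort", call. = FALSE)
  w <- hourly[hourly$hour < window_hours, , drop = FALSE]
  per_adm_mean <- function(v) tapply(w[[v]], w$admission_id, mean, na.rm = TRUE)
  d <- admissions
  for (v in c("map", "pao2", "spo2", "temperature", "rr", "peep", "p_peak")) {
    d[[paste0(v, "_mean")]] <- as.numeric(per_adm_mean(v)[d$admission_id])
  }
  d$fio2_mean <- 100 * as.numeric(per_adm_mean("fio2")[d$admission_id])
  d$vt_ml_mean <- 1000 * as.numeric(per_adm_mean("vt")[d$admission_id])
  mp_ok <- !is.na(w$vt) & !is.na(w$rr) & !is.na(w$peep) & !is.na(w$p_peak)
  wm <- w[mp_ok, , drop = FALSE]
  mp <- mechanical_power(wm$vt, wm$rr, wm$peep, wm$p_peak)
  d$mp_mean <- as.numeric(tapply(mp, wm$admission_id, mean)[d$admission_id])
  d$minute_ventilation_mean <-
    as.numeric(tapply(wm$vt * wm$rr, wm$admission_id, mean)[d$admission_id])
  d$driving_pressure_mean <-
    as.numeric(tapply(wm$p_peak - wm$peep, wm$admission_id,
                      mean)[d$admission_id])
  med <- d[d$admission_type == "medical", , drop = FALSE]
  sur <- d[d$admission_type == "surgical", , drop = FALSE]
  vars <- table_one_variables()
  rows <- list()
  fmt_ms <- function(x) sprintf("%.1f (%.1f)", mean(x, na.rm = TRUE),
                                stats::sd(x, na.rm = TRUE))
  fmt_mi <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    sprintf("%.1f (%.1f-%.1f)", q[2L], q[1L], q[3L])
  }
  test_p <- function(f, ...) {
    tryCatch(f(...), error = function(e) NA_real_)
  }
  for (v in names(vars$continuous)) {
    ok <- sum(!is.na(med[[v]])) >= 2 && sum(!is.na(sur[[v]])) >= 2
    p <- if (ok) {
      test_p(function() stats::t.test(med[[v]], sur[[v]],
                                      var.equal = TRUE)$p.value)
    } else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      variable = vars$continuous[[v]], type = "mean_sd", level = "",
      overall = fmt_ms(d[[v]]), medical = fmt_ms(med[[v]]),
      surgical = fmt_ms(sur[[v]]),
      test = if (ok) "t-test" else "NA (group too small)",
      p_value = p, stringsAsFactors = FALSE)
  }
  for (v in names(vars$skewed)) {
    ok <- sum(!is.na(med[[v]])) >= 2 && sum(!is.na(sur[[v]])) >= 2
    p <- if (ok) {
      test_p(function() stats::wilcox.test(med[[v]], sur[[v]],
                                           exact = FALSE)$p.value)
    } else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      variable = vars$skewed[[v]], type = "median_iqr", level = "",
      overall = fmt_mi(d[[v]]), medical = fmt_mi(med[[v]]),
      surgical = fmt_mi(sur[[v]]),
      test = if (ok) "Mann-Whitney" else "NA (group too small)",
      p_value = p, stringsAsFactors = FALSE)
  }
  for (v in names(vars$categorical)) {
    tab <- table(d[[v]], d$admission_type)
    ok <- nrow(med) >= 2 && nrow(sur) >= 2 && nrow(tab) >= 2
    p <- if (ok) {
      test_p(function() suppressWarnings(
        stats::chisq.test(table(d[[v]], d$admission_type))$p.value))
    } else NA_real_
    lev <- sort(unique(d[[v]]))
    for (k in seq_along(lev)) {
      cnt <- function(x) {
        m <- sum(x[[v]] == lev[k], na.rm = TRUE)
        sprintf("%d (%.1f)", m, 100 * m / max(nrow(x), 1L))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variable = vars$categorical[[v]], type = "n_pct", level = lev[k],
        overall = cnt(d), medical = cnt(med), surgical = cnt(sur),
        test = if (k == 1L) {
          if (ok) "chi-square" else "NA (group too small)"
        } else "",
        p_value = if (k == 1L) p else NA_real_, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## ---- configuration ------------------------------------------------------

parse_config_value <- function(x) {
  x <- trimws(x)
  if (toupper(x) %in% c("TRUE", "FALSE")) return(as.logical(toupper(x)))
  n <- suppressWarnings(as.numeric(x))
  if (!is.na(n)) return(n)
  if (grepl(",", x)) return(trimws(strsplit(x, ",")[[1L]]))
  x
}

#' Parse the plain-text pipeline configuration
#'
#' INI-style: `[section]` headers with `key = value` lines; `#` comments.
#' Values are coerced to logical/numeric where possible; comma-separated
#' values become vectors.
#'
#' @param path Config file path.
#' @return Nested named list (sections of key-value pairs).
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- list()
  section <- "global"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("\\[|\\]", "", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) {
      stop("read_pipeline_config: malformed line: ", ln, call. = FALSE)
    }
    cfg[[section]][[trimws(kv[1L])]] <-
      parse_config_value(paste(kv[-1L], collapse = "="))
  }
  cfg
}

cfg_get <- function(cfg, section, key, default) {
  v <- cfg[[section]][[key]]
  if (is.null(v)) default else v
}

VALID_ESTIMATORS <- c("backdoor_lr", "dml_forest", "dml_generic")

#' Run the full analysis pipeline
#'
#' Executes, in order: data acquisition (synthetic generation or CSV input),
#' inclusion filtering, the descriptive table, ATEs of median/max/min MP on
#' VFD28 for each configured estimator, subgroup CATEs (admission type,
#' diagnosis group, P/F strata), and - when enabled - the dynamic grid and
#' trajectory simulation. Every artifact is written under `out_dir` with the
#' parsed configuration and seeds echoed; report bodies contain no
#' timestamps, so equal config and seed reproduce them byte for byte.
#'
#' @param config Path to a config file ([read_pipeline_config()] format) or
#'   an equivalent nested list.
#' @param out_dir Output directory (created). `NULL` skips file output.
#' @param seed Overrides the config seed when non-`NULL`.
#' @return Object of class `cohort_report` (invisible when writing files).
#' @export
run_full_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  estimators <- cfg_get(cfg, "estimators", "estimators", VALID_ESTIMATORS)
  bad <- setdiff(estimators, VALID_ESTIMATORS)
  if (length(bad)) {
    stop("run_full_pipeline: unknown estimator tag(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  seed <- as.integer(seed %||% cfg_get(cfg, "global", "seed", 1))
  window <- cfg_get(cfg, "pipeline", "window_hours", 24)
  min_ch <- cfg_get(cfg, "pipeline", "min_complete_hours", 2)
  min_n <- cfg_get(cfg, "estimators", "min_n", 50)
  n_boot <- cfg_get(cfg, "estimators", "n_boot", 200)
  k_folds <- cfg_get(cfg, "estimators", "k_folds", 5)
  num_trees <- cfg_get(cfg, "estimators", "num_trees", 100)

  if (isTRUE(cfg_get(cfg, "synthetic", "use", TRUE))) {
    sc <- sim_config(
      n_admissions = cfg_get(cfg, "synthetic", "n_admissions", 500),
      frac_medical = cfg_get(cfg, "synthetic", "frac_medical", 0.417),
      true_ate_vfd = cfg_get(cfg, "synthetic", "true_ate_vfd", -0.15),
      true_pf_effect = cfg_get(cfg, "synthetic", "true_pf_effect", -20),
      mp_threshold_true = cfg_get(cfg, "synthetic", "mp_threshold_true", 17),
      missing_rate = cfg_get(cfg, "synthetic", "missing_rate", 0),
      max_hours = cfg_get(cfg, "synthetic", "max_hours", 48),
      seed = seed)
    cohort <- generate_cohort(sc)
    admissions <- cohort$admissions
    hourly <- cohort$hourly
  } else {
    hourly <- read_hourly_csv(cfg_get(cfg, "data", "hourly_csv",
                                      stop("data.hourly_csv required")))
    admissions <- read_admissions_csv(cfg_get(cfg, "data", "admissions_csv",
                                              stop("data.admissions_csv required")))
  }

  inc <- apply_inclusion(admissions, hourly, min_complete_hours = min_ch)
  t1 <- table_one(inc$admissions, inc$hourly, window_hours = window)
  at <- analysis_table(inc$admissions, inc$hourly, window_hours = window)
  adjustment <- c("age_band", "admission_type", "diagnosis_group", "apache_ii")

  ates <- list()
  for (est in estimators) {
    for (tv in c("mp_median", "mp_max", "mp_min")) {
      ates[[length(ates) + 1L]] <- run_estimator(
        est, at, tv, "vfd28", adjustment, seed = seed,
        n_boot = n_boot, k_folds = k_folds, num_trees = num_trees,
        drop_aliased = TRUE)
    }
  }

  cate_est <- cfg_get(cfg, "estimators", "cate_estimator", "backdoor_lr")
  cates <- list()
  for (grp in c("admission_type", "diagnosis_group", "pf_stratum")) {
    cates <- c(cates, cate_by_subgroup(
      at, grp, "mp_median", "vfd28", adjustment, estimator = cate_est,
      min_n = min_n, seed = seed, n_boot = n_boot, k_folds = k_folds,
      num_trees = num_trees, drop_aliased = TRUE))
  }

  grid <- NULL
  if (isTRUE(cfg_get(cfg, "grid", "enabled", FALSE))) {
    grid <- fit_cate_grid(
      inc$hourly, inc$admissions,
      hours = seq(cfg_get(cfg, "grid", "hour_min", 0),
                  cfg_get(cfg, "grid", "hour_max", 40)),
      thresholds = seq(cfg_get(cfg, "grid", "threshold_min", 0),
                       cfg_get(cfg, "grid", "threshold_max", 40),
                       by = cfg_get(cfg, "grid", "threshold_step", 1)),
      outcome_lead = cfg_get(cfg, "grid", "outcome_lead", 1),
      min_cell_n = cfg_get(cfg, "grid", "min_cell_n", 50),
      seed = seed)
  }
  trajectory <- NULL
  if (!is.null(grid) && isTRUE(cfg_get(cfg, "trajectory", "enabled", FALSE))) {
    tc <- trajectory_config(
      initial_mp = cfg_get(cfg, "trajectory", "initial_mp", 40),
      noise_level = cfg_get(cfg, "trajectory", "noise_level", 0.4),
      horizon_hours = cfg_get(cfg, "trajectory", "horizon_hours",
                              length(grid$hours)),
      perturbation_range = c(cfg_get(cfg, "trajectory", "perturb_low", 5),
                             cfg_get(cfg, "trajectory", "perturb_high", 40)),
      seed = seed)
    trajectory <- simulate_trajectory(grid, tc)
  }

  report <- structure(list(
    counts = inc$counts, table_one = t1,
    ate_estimates = structure(ates, class = "effect_estimate_list"),
    cate_estimates = structure(cates, class = "effect_estimate_list"),
    grid = grid, trajectory = trajectory, config = cfg, seed = seed,
    n_analysis = nrow(at)), class = "cohort_report")
  if (!is.null(out_dir)) {
    write_cohort_report(report, out_dir)
    return(invisible(report))
  }
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("cohort_report (seed", x$seed, ")\n")
  cat("  inclusion counts:",
      paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", "),
      "\n")
  cat("  analysis admissions:", x$n_analysis, "\n")
  cat("  ATE rows:", length(x$ate_estimates),
      "| CATE rows:", length(x$cate_estimates), "\n")
  invisible(x)
}

#' Write all report artifacts
#'
#' Emits `report.txt` (human-readable body, no timestamps), `estimates.csv`
#' (all ATE and CATE rows, tidy), `table_one.csv`, `inclusion_counts.txt`,
#' `config_echo.txt`, and grid/trajectory exports when those stages ran.
#'
#' @param report A `cohort_report`.
#' @param out_dir Output directory.
#' @return Invisibly, `out_dir`.
#' @export
write_cohort_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  est <- estimates_table(c(report$ate_estimates, report$cate_estimates))
  utils::write.csv(format(est, digits = 10, trim = TRUE, scientific = FALSE),
                   file.path(out_dir, "estimates.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  utils::write.csv(format(report$table_one, digits = 6, trim = TRUE,
                          scientific = FALSE),
                   file.path(out_dir, "table_one.csv"),
                   row.names = FALSE, quote = TRUE, na = "")
  writeLines(sprintf("%s=%d", names(report$counts), report$counts),
             file.path(out_dir, "inclusion_counts.txt"))
  echo <- unlist(lapply(names(report$config), function(s) {
    kv <- report$config[[s]]
    sprintf("%s.%s=%s", s, names(kv),
            vapply(kv, function(v) paste(format(v), collapse = ","), ""))
  }))
  writeLines(c(sprintf("seed=%d", report$seed), sort(echo)),
             file.path(out_dir, "config_echo.txt"))

  con <- file(file.path(out_dir, "report.txt"), "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("ventcausal cohort report (seed ", report$seed, ")")
  wl("")
  wl("Inclusion counts: ",
     paste(sprintf("%s=%d", names(report$counts), report$counts),
           collapse = ", "))
  wl("Analysis admissions: ", report$n_analysis)
  wl("")
  wl("Effect estimates:")
  for (i in seq_len(nrow(est))) {
    r <- est[i, ]
    wl(sprintf("  %s %s %s [%s] %s: %s (%s, %s) n=%s%s",
               r$estimand, r$treatment_var, r$treatment_coding,
               r$estimator_tag, r$subgroup,
               format(r$point, digits = 6), format(r$ci_low, digits = 6),
               format(r$ci_high, digits = 6), r$n,
               if (isTRUE(as.logical(r$suppressed))) " [suppressed]" else ""))
  }
  if (!is.null(report$grid)) {
    write_grid_csv(report$grid, file.path(out_dir, "grid.csv"))
    write_grid_matrix(report$grid, file.path(out_dir, "grid_matrix.csv"))
    wl("")
    wl("Grid: ", length(report$grid$hours), " hours x ",
       length(report$grid$thresholds), " thresholds (",
       sum(!report$grid$mask), " unmasked cells; ",
       sum(!report$grid$mask), " models fitted)")
  }
  if (!is.null(report$trajectory)) {
    write_trajectory_csv(report$trajectory,
                         file.path(out_dir, "trajectory.csv"))
    write_trajectory_summary(report$trajectory,
                             file.path(out_dir, "trajectory_summary.txt"))
    r <- trajectory_report(report$trajectory)
    wl("Trajectory: ", r$n_hours, " hours, ", r$n_perturbed,
       " perturbed, cumulative effect ",
       format(r$cumulative_cate, digits = 6))
  }
  invisible(out_dir)
}

## ---- external schema mapping stub --------------------------------------

#' Map an external (e.g. research-database) schema onto the standard tables
#'
#' The mapping file uses the configuration format: sections `[hourly]` and
#' `[admissions]`, lines `standard_name = source_column[, unit]`. Supported
#' unit conversions: `ml` -> litres, `percent` -> fraction. Standard columns
#' already present under their own names need no mapping line. Database
#' connectivity/ETL is out of scope: this is a schema-mapping stub for
#' pre-extracted tables.
#'
#' @param mapping Path to a mapping file or an equivalent nested list.
#' @param hourly_raw,admissions_raw Raw source tables.
#' @return List with standardised `hourly` (internal units) and `admissions`.
#' @export
map_external_schema <- function(mapping, hourly_raw, admissions_raw) {
  cfg <- if (is.character(mapping)) read_pipeline_config(mapping) else mapping
  internal_hourly <- c("admission_id", "hour", "vt", "rr", "peep", "p_peak",
                       "fio2", "spo2", "pao2", "paco2", "ph", "wbc",
                       "temperature", "map", "mode_spontaneous")
  convert <- function(x, unit) {
    switch(unit, ml = x / 1000, percent = x / 100, x)
  }
  map_table <- function(raw, section, required) {
    spec <- cfg[[section]] %||% list()
    out <- list()
    gaps <- character(0)
    for (std in required) {
      if (std %in% names(spec)) {
        v <- spec[[std]]
        src <- v[1L]
        unit <- if (length(v) > 1L) v[2L] else "identity"
        if (!src %in% names(raw)) {
          gaps <- c(gaps, std)
          next
        }
        out[[std]] <- convert(raw[[src]], unit)
      } else if (std %in% names(raw)) {
        out[[std]] <- raw[[std]]
      } else {
        gaps <- c(gaps, std)
      }
    }
    list(table = out, gaps = gaps)
  }
  h <- map_table(hourly_raw, "hourly", internal_hourly)
  a <- map_table(admissions_raw, "admissions", ADMISSION_COLUMNS)
  gaps <- c(h$gaps, a$gaps)
  if (length(gaps)) {
    stop("map_external_schema: unmapped required column(s): ",
         paste(gaps, collapse = ", "), call. = FALSE)
  }
  list(hourly = as.data.frame(h$table, stringsAsFactors = FALSE),
       admissions = as.data.frame(a$table, stringsAsFactors = FALSE))
}
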