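# Standard CSV schemas and the admission-level analysis table.
#
# External hourly schema (one row per admission-hour): admission_id, hour,
# vt_ml, rr, peep, p_peak, fio2, spo2, pao2, paco2, ph, wbc, temperature,
# map, mode_spontaneous (0/1). Tidal volume is stored in millilitres and
# converted to litres at read time; FiO2 values in the percent dialect are
# normalised to fractions. Admission schema: admission_id, age_band,
# admission_type, diagnosis_group, apache_ii, intubation_duration_hours,
# death_day (empty = alive/censored).

HOURLY_COLUMNS <- c("admission_id", "hour", "vt_ml", "rr", "peep", "p_peak",
                    "fio2", "spo2", "pao2", "paco2", "ph", "wbc",
                    "temperature", "map", "mode_spontaneous")

ADMISSION_COLUMNS <- c("admission_id", "age_band", "admission_type",
                       "diagnosis_group", "apache_ii",
                       "intubation_duration_hours", "death_day")

#' Read / write the hourly CSV schema
#'
#' @param path CSV file path.
#' @return `read_hourly_csv()` returns the internal hourly table (`vt` in
#'   litres, `fio2` as a fraction).
#' @export
read_hourly_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(HOURLY_COLUMNS, names(x))
  if (length(missing)) {
    stop("read_hourly_csv: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x$vt <- x$vt_ml / 1000
  x$vt_ml <- NULL
  x$fio2 <- ifelse(!is.na(x$fio2) & x$fio2 > 1, x$fio2 / 100, x$fio2)
  x
}

#' @rdname read_hourly_csv
#' @param hourly Internal hourly table (`vt` in litres).
#' @export
write_hourly_csv <- function(hourly, path) {
  out <- hourly
  out$vt_ml <- out$vt * 1000
  out$vt <- NULL
  out <- out[, HOURLY_COLUMNS]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write the admission CSV schema
#' @param path CSV file path.
#' @return `read_admissions_csv()` returns the admission table (`death_day`
#'   `NA` when the field is empty).
#' @export
read_admissions_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("NA", ""))
  missing <- setdiff(ADMISSION_COLUMNS, names(x))
  if (length(missing)) {
    stop("read_admissions_csv: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x$death_day <- as.integer(x$death_day)   # all-missing columns parse as logical
  x
}

#' @rdname read_admissions_csv
#' @param admissions Admission table.
#' @export
write_admissions_csv <- function(admissions, path) {
  out <- admissions[, intersect(c(ADMISSION_COLUMNS, "vfd28"),
                                names(admissions))]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Build the admission-level analysis table
#'
#' Merges admission covariates with windowed ventilator summaries
#' ([aggregate_mp_cohort()]), the VFD28 composite outcome, and the mean
#' early P/F ratio with its stratum (`<200`, `200-300`, `>=300`). Admissions
#' without a complete MP hour in the window are dropped (inclusion filtering
#' normally runs first).
#'
#' @param admissions Admission table (standard schema).
#' @param hourly Hourly table (internal units).
#' @param window_hours Aggregation window, default 24.
#' @return Data frame with one row per analysable admission.
#' @export
analysis_table <- function(admissions, hourly, window_hours = 24) {
  vs <- aggregate_mp_cohort(hourly, window_hours)
  w <- hourly[hourly$hour < window_hours & !is.na(hourly$pao2) &
                !is.na(hourly$fio2), , drop = FALSE]
  pf <- pf_ratio(w$pao2, w$fio2)
  pf_mean <- tapply(pf, w$admission_id, mean)
  out <- merge(admissions, vs, by = "admission_id", sort = TRUE)
  out$pf_mean <- as.numeric(pf_mean[out$admission_id])
  out$pf_stratum <- cut(out$pf_mean, c(-Inf, 200, 300, Inf),
                        labels = c("<200", "200-300", ">=300"),
                        right = FALSE)
  out$pf_stratum <- as.character(out$pf_stratum)
  if (!"vfd28" %in% names(out)) {
    out$vfd28 <- vfd28(out$intubation_duration_hours, out$death_day)
  }
  rownames(out) <- NULL
  out
}
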