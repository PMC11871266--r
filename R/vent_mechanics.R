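# Ventilator mechanics: mechanical power, P/F ratio, per-admission MP
# aggregates and the VFD28 composite outcome.

#' Mechanical power delivered by the ventilator
#'
#' Computes mechanical power (MP) in joules per minute from tidal volume,
#' respiratory rate, PEEP and peak inspiratory pressure using the simplified
#' bedside formula
#' \deqn{MP = 0.098 \cdot V_t \cdot RR \cdot (PEEP + P_{insp}),}
#' where \eqn{P_{insp}} is the difference between peak inspiratory pressure
#' and PEEP, so the bracket collapses to the peak pressure. PEEP therefore
#' enters only through the validity constraint `p_peak >= peep`; it is still
#' required so that inconsistent records are rejected rather than silently
#' accepted.
#'
#' @param vt Tidal volume in litres (not mL). Must be > 0.
#' @param rr Respiratory rate, breaths/min. Must be >= 0.
#' @param peep Positive end-expiratory pressure, cmH2O. Must satisfy
#'   `0 <= peep <= p_peak`.
#' @param p_peak Peak inspiratory pressure, cmH2O.
#' @return Mechanical power in J/min. Vectorised; `NA` propagates.
#' @examples
#' mechanical_power(0.5, 15, 5, 20) # 14.7 J/min
#' @export
mechanical_power <- function(vt, rr, peep, p_peak) {
  bad_vt <- !is.na(vt) & vt <= 0
  if (any(bad_vt)) {
    stop("mechanical_power: tidal volume must be positive (litres); got ",
         vt[bad_vt][1L], call. = FALSE)
  }
  if (any(!is.na(rr) & rr < 0)) {
    stop("mechanical_power: respiratory rate must be non-negative", call. = FALSE)
  }
  if (any(!is.na(peep) & peep < 0)) {
    stop("mechanical_power: PEEP must be non-negative", call. = FALSE)
  }
  bad_pk <- !is.na(peep) & !is.na(p_peak) & p_peak < peep
  if (any(bad_pk)) {
    stop("mechanical_power: peak pressure below PEEP (p_peak = ",
         p_peak[bad_pk][1L], ", peep = ", peep[bad_pk][1L], ")", call. = FALSE)
  }
  # peep + (p_peak - peep) == p_peak
  0.098 * vt * rr * p_peak
}

#' PaO2/FiO2 (P/F) ratio
#'
#' Oxygenation severity marker: arterial oxygen tension divided by the
#' inspired oxygen fraction. FiO2 values in (1, 100] are interpreted as
#' percentages and divided by 100 (both dialects occur in ICU exports);
#' values <= 1 are taken as fractions.
#'
#' @param pao2 PaO2 in mmHg, > 0.
#' @param fio2 FiO2 as a fraction in \[0.21, 1\] or a percentage in (1, 100\].
#' @return P/F ratio (mmHg). Vectorised.
#' @examples
#' pf_ratio(100, 0.5)  # 200
#' pf_ratio(100, 50)   # 200, percent dialect
#' @export
pf_ratio <- function(pao2, fio2) {
  if (any(!is.na(pao2) & pao2 <= 0)) {
    stop("pf_ratio: PaO2 must be positive", call. = FALSE)
  }
  f <- ifelse(!is.na(fio2) & fio2 > 1 & fio2 <= 100, fio2 / 100, fio2)
  if (any(!is.na(f) & (f < 0.21 - 1e-9 | f > 1))) {
    stop("pf_ratio: FiO2 outside [0.21, 1] after percent normalisation",
         call. = FALSE)
  }
  pao2 / f
}

#' SpO2/FiO2 ratio
#'
#' Pulse-oximetric analogue of [pf_ratio()], offered as an optional
#' oxygenation column; the package's models use PaO2/FiO2 as primary.
#'
#' @param spo2 SpO2 in percent (0-100).
#' @param fio2 As in [pf_ratio()].
#' @return S/F ratio.
#' @export
sf_ratio <- function(spo2, fio2) {
  if (any(!is.na(spo2) & (spo2 < 0 | spo2 > 100))) {
    stop("sf_ratio: SpO2 must be in [0, 100] percent", call. = FALSE)
  }
  f <- ifelse(!is.na(fio2) & fio2 > 1 & fio2 <= 100, fio2 / 100, fio2)
  spo2 / f
}

#' Windowed per-admission ventilator summary
#'
#' Aggregates the hourly mechanical power of one admission over an early
#' window (default: first 24 h, the usual descriptive window) into
#' median/max/min MP, plus mean driving pressure (peak minus PEEP; plateau
#' pressure is not in the data model) and mean minute ventilation. Hours with
#' any of the four MP inputs missing are dropped.
#'
#' @param records Data frame of hourly rows for a single admission with
#'   columns `hour`, `vt` (litres), `rr`, `peep`, `p_peak`.
#' @param window_hours Width of the aggregation window; hours in
#'   `[0, window_hours)` are used. Default 24.
#' @return A one-row data frame of class `vent_summary`: `admission_id`,
#'   `mp_median`, `mp_max`, `mp_min`, `driving_pressure_mean`,
#'   `minute_ventilation_mean`, `n_hours_used`.
#' @export
aggregate_mp <- function(records, window_hours = 24) {
  stopifnot(is.data.frame(records))
  if (length(unique(records$admission_id)) > 1L) {
    stop("aggregate_mp: records span more than one admission", call. = FALSE)
  }
  w <- records[records$hour >= 0 & records$hour < window_hours, , drop = FALSE]
  complete <- !is.na(w$vt) & !is.na(w$rr) & !is.na(w$peep) & !is.na(w$p_peak)
  w <- w[complete, , drop = FALSE]
  if (nrow(w) == 0L) {
    stop("aggregate_mp: insufficient data - no complete MP hour in window",
         call. = FALSE)
  }
  mp <- mechanical_power(w$vt, w$rr, w$peep, w$p_peak)
  out <- data.frame(
    admission_id = w$admission_id[1L],
    mp_median = stats::median(mp),
    mp_max = max(mp),
    mp_min = min(mp),
    driving_pressure_mean = mean(w$p_peak - w$peep),
    minute_ventilation_mean = mean(w$vt * w$rr),
    n_hours_used = nrow(w),
    stringsAsFactors = FALSE
  )
  class(out) <- c("vent_summary", class(out))
  out
}

#' Windowed MP summaries for a whole cohort
#'
#' Vectorised counterpart of [aggregate_mp()]: one row per admission with at
#' least one complete MP hour inside the window; admissions with none are
#' omitted (upstream inclusion filters normally remove them first).
#'
#' @inheritParams aggregate_mp
#' @param hourly Hourly table for many admissions (schema of
#'   [read_hourly_csv()]).
#' @return Data frame, one row per retained admission, columns as in
#'   [aggregate_mp()].
#' @export
aggregate_mp_cohort <- function(hourly, window_hours = 24) {
  w <- hourly[hourly$hour >= 0 & hourly$hour < window_hours, , drop = FALSE]
  ok <- !is.na(w$vt) & !is.na(w$rr) & !is.na(w$peep) & !is.na(w$p_peak)
  w <- w[ok, , drop = FALSE]
  if (nrow(w) == 0L) {
    return(data.frame(admission_id = character(0), mp_median = numeric(0),
                      mp_max = numeric(0), mp_min = numeric(0),
                      driving_pressure_mean = numeric(0),
                      minute_ventilation_mean = numeric(0),
                      n_hours_used = integer(0)))
  }
  mp <- mechanical_power(w$vt, w$rr, w$peep, w$p_peak)
  sp <- split(seq_len(nrow(w)), w$admission_id)
  res <- lapply(sp, function(ix) {
    c(mp_median = stats::median(mp[ix]), mp_max = max(mp[ix]),
      mp_min = min(mp[ix]),
      driving_pressure_mean = mean(w$p_peak[ix] - w$peep[ix]),
      minute_ventilation_mean = mean(w$vt[ix] * w$rr[ix]),
      n_hours_used = length(ix))
  })
  out <- as.data.frame(do.call(rbind, res))
  out$admission_id <- names(sp)
  rownames(out) <- NULL
  out[, c("admission_id", "mp_median", "mp_max", "mp_min",
          "driving_pressure_mean", "minute_ventilation_mean", "n_hours_used")]
}

#' Ventilator-free days at day 28 (VFD28)
#'
#' Composite outcome combining ventilation duration and 28-day mortality:
#' a patient who dies on or before day 28 scores 0; otherwise the score is
#' `max(0, 28 - ceiling(duration_hours / 24))` days. A single continuous
#' ventilation episode is assumed (reintubation is out of scope).
#'
#' @param intubation_duration_hours Hours of invasive ventilation, >= 0.
#' @param death_day Day of death (integer >= 0) or `NA`/`NULL` if alive or
#'   censored beyond day 28.
#' @return Integer days in \[0, 28\]. Vectorised over both arguments.
#' @examples
#' vfd28(240, NA)  # 18: ten days ventilated, survived
#' vfd28(120, 20)  # 0: died before day 28
#' vfd28(720, NA)  # 0: ventilated past day 28
#' @export
vfd28 <- function(intubation_duration_hours, death_day = NA) {
  if (is.null(death_day)) death_day <- NA
  if (any(!is.na(intubation_duration_hours) & intubation_duration_hours < 0)) {
    stop("vfd28: negative intubation duration", call. = FALSE)
  }
  if (any(!is.na(death_day) & death_day < 0)) {
    stop("vfd28: negative death day", call. = FALSE)
  }
  n <- max(length(intubation_duration_hours), length(death_day))
  dur <- rep_len(intubation_duration_hours, n)
  dd <- rep_len(death_day, n)
  v <- pmax(0L, 28L - as.integer(ceiling(dur / 24)))
  v[!is.na(dd) & dd <= 28] <- 0L
  v
}
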