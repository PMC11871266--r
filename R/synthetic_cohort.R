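# Synthetic ICU cohort generator.
#
# Structural equations follow the package's default ventilation DAG:
# baseline covariates (age band, admission type, diagnosis) -> latent disease
# severity -> labs/vitals (WBC, temperature, pH, MAP, PaCO2) and clinician
# ventilator policy (RR, inspiratory pressure, PEEP) -> mechanical power;
# lagged MP + severity -> hourly P/F; the latent ventilation course (severity,
# median early MP) -> intubation duration and 28-day mortality -> VFD28.
# Severity is a deterministic function of the OBSERVED admission covariates
# (age band, admission type, diagnosis group, APACHE II), so adjusting for
# those recovers the configured true effects exactly; the hourly labs are
# noisy children of severity, as in the DAG.

DIAGNOSIS_GROUPS <- c("cardiothoracic_surgery", "neurosurgery",
                      "vascular_surgery", "trauma", "cardiac",
                      "respiratory_failure", "infection", "shock", "other")

AGE_BANDS <- c("18-39", "40-49", "50-59", "60-69", "70-79", "80+")

#' Default diagnosis mix per admission arm
#'
#' Proportions sum to one within each arm; loosely calibrated to the
#' indication frequencies of a large mixed medical/surgical ICU population.
#' @return Named list with `medical` and `surgical` probability vectors.
#' @export
default_diagnosis_mix <- function() {
  list(
    medical = c(shock = 0.55, respiratory_failure = 0.20, infection = 0.15,
                cardiac = 0.08, other = 0.02),
    surgical = c(cardiothoracic_surgery = 0.69, neurosurgery = 0.12,
                 vascular_surgery = 0.10, trauma = 0.05, other = 0.04)
  )
}

#' Default residual standard deviations for the generator
#' @return Named numeric vector (units of the respective variable).
#' @export
default_noise_sd <- function() {
  c(rr = 2.5, p_insp = 3, peep = 1.5, vt = 0.05, fio2 = 0.08, pf = 25,
    wbc = 3, temperature = 1, ph = 0.05, map = 10, paco2 = 5,
    apache = 4, vfd = 3)
}

#' Configuration for the synthetic cohort generator
#'
#' @param n_admissions Number of admissions (>= 1).
#' @param frac_medical Proportion of medical (vs surgical) admissions.
#' @param diagnosis_mix Named list `medical`/`surgical` of diagnosis-group
#'   proportions, each summing to 1 (tolerance 1e-9); groups must come from
#'   the package's closed vocabulary.
#' @param true_ate_vfd True causal effect of median early MP on VFD28, in
#'   days per J/min (default -0.15).
#' @param true_cate_map Optional named vector of cohort-specific effects
#'   (days per J/min); names are admission types (`medical`, `surgical`) or
#'   diagnosis groups. `NULL` (default) means a homogeneous effect
#'   `true_ate_vfd`.
#' @param true_pf_effect Marginal effect of the previous hour's MP on the
#'   next-hour P/F ratio (ratio units per J/min), applied only to MP in
#'   excess of `mp_threshold_true` (a hinge: zero effect below the
#'   change-point). Default -2.
#' @param mp_threshold_true Change-point, J/min (default 17).
#' @param true_vfd_step Additional step effect on VFD28 (days) of median MP
#'   above `mp_threshold_true`; default 0 (used for binary-threshold
#'   recovery experiments).
#' @param noise_sd_map Named vector of residual SDs, see
#'   [default_noise_sd()]. All SDs must be >= 0.
#' @param missing_rate Probability in \[0, 1) that each ventilator field is
#'   missing (applied by [inject_missingness()] inside generation when > 0).
#' @param max_hours Cap on stored hourly records per admission (>= 1).
#' @param confounding_strength Multiplier on the severity -> ventilator-policy
#'   coefficients (0 = unconfounded exposure).
#' @param nonlinear_confounding If `TRUE`, a smooth nonlinear severity term
#'   enters both the ventilator policy and the outcome, so linear adjustment
#'   is misspecified while flexible nuisance learners are not.
#' @param spontaneous_rate Per-hour probability of a spontaneous-mode flag.
#' @param mortality_shift Downward shift (days) of the latent ventilation
#'   course; raises 28-day mortality at the cost of clamping the configured
#'   linear truth. Default 0.
#' @param seed Integer seed; all sub-streams are derived from it by fixed
#'   offsets.
#' @return Object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_admissions = 1000, frac_medical = 0.417,
                       diagnosis_mix = default_diagnosis_mix(),
                       true_ate_vfd = -0.15, true_cate_map = NULL,
                       true_pf_effect = -2, mp_threshold_true = 17,
                       true_vfd_step = 0,
                       noise_sd_map = default_noise_sd(),
                       missing_rate = 0, max_hours = 48,
                       confounding_strength = 1,
                       nonlinear_confounding = FALSE,
                       spontaneous_rate = 0.02,
                       mortality_shift = 0,
                       seed = 1L) {
  fail <- function(field, why) {
    stop("sim_config: invalid `", field, "`: ", why, call. = FALSE)
  }
  if (!is.numeric(n_admissions) || n_admissions < 1) fail("n_admissions", ">= 1 required")
  if (!is.numeric(frac_medical) || frac_medical < 0 || frac_medical > 1) {
    fail("frac_medical", "must lie in [0, 1]")
  }
  if (!is.list(diagnosis_mix) ||
      !all(c("medical", "surgical") %in% names(diagnosis_mix))) {
    fail("diagnosis_mix", "need a list with `medical` and `surgical` entries")
  }
  for (arm in c("medical", "surgical")) {
    mx <- diagnosis_mix[[arm]]
    if (any(mx < 0) || abs(sum(mx) - 1) > 1e-9) {
      fail("diagnosis_mix", paste0(arm, " proportions must be >= 0 and sum to 1"))
    }
    if (!all(names(mx) %in% DIAGNOSIS_GROUPS)) {
      fail("diagnosis_mix", paste0("unknown diagnosis group(s): ",
                                   paste(setdiff(names(mx), DIAGNOSIS_GROUPS),
                                         collapse = ", ")))
    }
  }
  if (!is.null(true_cate_map)) {
    ok <- names(true_cate_map) %in% c("medical", "surgical", DIAGNOSIS_GROUPS)
    if (is.null(names(true_cate_map)) || !all(ok)) {
      fail("true_cate_map", "names must be admission types or diagnosis groups")
    }
  }
  if (any(noise_sd_map < 0)) fail("noise_sd_map", "SDs must be >= 0")
  need_sd <- names(default_noise_sd())
  if (!all(need_sd %in% names(noise_sd_map))) {
    fail("noise_sd_map", paste0("missing entries: ",
                                paste(setdiff(need_sd, names(noise_sd_map)),
                                      collapse = ", ")))
  }
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1) {
    fail("missing_rate", "must lie in [0, 1)")
  }
  if (!is.numeric(max_hours) || max_hours < 1) fail("max_hours", ">= 1 required")
  if (spontaneous_rate < 0 || spontaneous_rate >= 1) {
    fail("spontaneous_rate", "must lie in [0, 1)")
  }
  if (!is.numeric(seed) || is.na(seed)) fail("seed", "integer required")
  structure(list(
    n_admissions = as.integer(n_admissions), frac_medical = frac_medical,
    diagnosis_mix = diagnosis_mix, true_ate_vfd = true_ate_vfd,
    true_cate_map = true_cate_map, true_pf_effect = true_pf_effect,
    mp_threshold_true = mp_threshold_true, true_vfd_step = true_vfd_step,
    noise_sd_map = noise_sd_map, missing_rate = missing_rate,
    max_hours = as.integer(max_hours),
    confounding_strength = confounding_strength,
    nonlinear_confounding = isTRUE(nonlinear_confounding),
    spontaneous_rate = spontaneous_rate, mortality_shift = mortality_shift,
    seed = as.integer(seed)), class = "sim_config")
}

# Fixed-offset sub-stream seeds derived from one global seed.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 99991 * k) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Numeric score per age band (standardised-ish), used inside severity.
age_band_score <- function(band) {
  sc <- c("18-39" = -1.7, "40-49" = -1.0, "50-59" = -0.45,
          "60-69" = 0.15, "70-79" = 0.65, "80+" = 1.2)
  unname(sc[band])
}

diag_severity_score <- function(diag) {
  sc <- c(shock = 0.9, respiratory_failure = 0.8, infection = 0.6,
          cardiac = 0.5, trauma = 0.3, neurosurgery = 0.1,
          vascular_surgery = 0.0, cardiothoracic_surgery = -0.3, other = 0.2)
  unname(sc[diag])
}

#' Generate a synthetic ICU cohort with known causal truth
#'
#' See the module header for the structural equations. The generated joint
#' distribution is confounded: sicker patients receive higher mechanical
#' power and also have worse outcomes, so the unadjusted MP coefficient is
#' biased while regression adjusting for the generator's confounders
#' (`age_band`, `admission_type`, `diagnosis_group`, `apache_ii`) has
#' expectation `true_ate_vfd` (or the cohort-specific values in
#' `true_cate_map`). Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Object of class `synthetic_cohort`: list with `admissions`
#'   (admission-level table following the standard schema plus `vfd28`),
#'   `hourly` (long hourly table, `vt` in litres), `truth` (the effect
#'   parameters, threshold, and the generator's confounder names) and
#'   `seed_used`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  n <- config$n_admissions
  H <- config$max_hours
  sd <- config$noise_sd_map
  cs <- config$confounding_strength

  ## --- admission-level draws -------------------------------------------
  set.seed(derive_seed(config$seed, 1L))
  admission_id <- sprintf("adm%06d", seq_len(n))
  band_p <- c(0.078, 0.078, 0.165, 0.286, 0.293, 0.100)
  age_band <- sample(AGE_BANDS, n, replace = TRUE, prob = band_p / sum(band_p))
  medical <- stats::rbinom(n, 1L, config$frac_medical)
  admission_type <- ifelse(medical == 1L, "medical", "surgical")
  diagnosis_group <- character(n)
  for (arm in c("medical", "surgical")) {
    ix <- which(admission_type == arm)
    mx <- config$diagnosis_mix[[arm]]
    if (length(ix)) {
      diagnosis_group[ix] <- sample(names(mx), length(ix), replace = TRUE,
                                    prob = mx)
    }
  }
  age_z <- age_band_score(age_band)
  dsev <- diag_severity_score(diagnosis_group)
  apache_ii <- clamp(round(16 + 3.5 * medical + 2 * age_z + 2.5 * dsev +
                             stats::rnorm(n, 0, sd[["apache"]])), 0, 50)
  # deterministic in the observed covariates -> adjustment closes the backdoor
  severity <- 0.18 * (apache_ii - 19) + 0.25 * medical + 0.15 * age_z +
    0.4 * dsev
  sev_pol <- if (config$nonlinear_confounding) {
    severity + 0.8 * (severity^2 - 1)
  } else severity

  ## --- hourly processes (n x H matrices) --------------------------------
  set.seed(derive_seed(config$seed, 2L))
  S <- matrix(severity, n, H)
  SP <- matrix(sev_pol, n, H)
  rr <- clamp(17 + 2.2 * cs * SP + matrix(stats::rnorm(n * H, 0, sd[["rr"]]), n, H),
              6, 45)
  peep <- clamp(7.5 + 1.2 * cs * S + matrix(stats::rnorm(n * H, 0, sd[["peep"]]), n, H),
                3, 20)
  p_insp <- clamp(13 + 2.8 * cs * SP + matrix(stats::rnorm(n * H, 0, sd[["p_insp"]]), n, H),
                  2, 40)
  p_peak <- peep + p_insp
  vt <- clamp(0.48 + matrix(stats::rnorm(n * H, 0, sd[["vt"]]), n, H), 0.2, 0.9)
  mp <- 0.098 * vt * rr * p_peak
  fio2 <- clamp(0.45 + 0.06 * S + matrix(stats::rnorm(n * H, 0, sd[["fio2"]]), n, H),
                0.21, 1)
  wbc <- clamp(10.5 + 2 * S + matrix(stats::rnorm(n * H, 0, sd[["wbc"]]), n, H),
               0.5, 60)
  temperature <- 35.8 - 0.25 * S +
    matrix(stats::rnorm(n * H, 0, sd[["temperature"]]), n, H)
  ph <- clamp(7.39 - 0.04 * S + matrix(stats::rnorm(n * H, 0, sd[["ph"]]), n, H),
              6.9, 7.7)
  map <- clamp(75 + 1.5 * S + matrix(stats::rnorm(n * H, 0, sd[["map"]]), n, H),
               35, 160)
  paco2 <- clamp(40 + 2.5 * S + matrix(stats::rnorm(n * H, 0, sd[["paco2"]]), n, H),
                 15, 120)
  # lagged-MP hinge effect on the P/F trajectory: marginal effect
  # true_pf_effect (ratio units per J/min) above the change-point, zero
  # below it; no effect at hour 0 (no lagged exposure yet).
  mp_lag <- cbind(NA_real_, mp[, -H, drop = FALSE])
  excess <- pmax(mp_lag - config$mp_threshold_true, 0)
  excess[is.na(excess)] <- 0
  pf_base <- pmax(60, 300 - 55 * severity)
  pf <- pmax(40, matrix(pf_base, n, H) + config$true_pf_effect * excess +
               matrix(stats::rnorm(n * H, 0, sd[["pf"]]), n, H))
  pao2 <- pf * fio2
  spo2 <- clamp(88 + 0.04 * pf + matrix(stats::rnorm(n * H, 0, 1), n, H), 50, 100)
  mode_spont <- matrix(stats::rbinom(n * H, 1L, config$spontaneous_rate), n, H)

  ## --- outcomes ----------------------------------------------------------
  set.seed(derive_seed(config$seed, 3L))
  w <- min(24L, H)
  mp_w <- mp[, seq_len(w), drop = FALSE]
  sp_w <- mode_spont[, seq_len(w), drop = FALSE] == 1L
  mp_expo <- vapply(seq_len(n), function(i) {
    x <- mp_w[i, !sp_w[i, ]]
    if (!length(x)) x <- mp_w[i, ]
    stats::median(x)
  }, numeric(1))
  slope <- rep(config$true_ate_vfd, n)
  if (!is.null(config$true_cate_map)) {
    cm <- config$true_cate_map
    by_type <- names(cm) %in% c("medical", "surgical")
    if (any(by_type)) {
      m <- cm[by_type][admission_type]
      slope[!is.na(m)] <- m[!is.na(m)]
    }
    if (any(!by_type)) {
      m <- cm[!by_type][diagnosis_group]
      slope[!is.na(m)] <- m[!is.na(m)]
    }
  }
  sev_out <- if (config$nonlinear_confounding) {
    severity + 1.3 * (severity^2 - 1)
  } else severity
  # Intercept keeps the latent course well below the 27-day ceiling implied
  # by the 24 h minimum ventilation episode: top-censoring there would leak
  # into the MP coefficient through its correlation with severity.
  latent <- 18 - 2.4 * sev_out + slope * mp_expo +
    config$true_vfd_step * (mp_expo > config$mp_threshold_true) +
    stats::rnorm(n, 0, sd[["vfd"]]) - config$mortality_shift
  died <- latent < 0
  death_day <- rep(NA_integer_, n)
  if (any(died)) death_day[died] <- sample(1:28, sum(died), replace = TRUE)
  duration <- clamp(24 * (28 - latent), 24, 1080)
  n_hours <- pmin(H, as.integer(ceiling(duration)))

  admissions <- data.frame(
    admission_id = admission_id, age_band = age_band,
    admission_type = admission_type, diagnosis_group = diagnosis_group,
    apache_ii = as.numeric(apache_ii),
    intubation_duration_hours = duration, death_day = death_day,
    stringsAsFactors = FALSE)
  admissions$vfd28 <- vfd28(admissions$intubation_duration_hours,
                            admissions$death_day)

  keep <- rep(seq_len(n), n_hours)
  hr <- sequence(n_hours) - 1L
  flat <- cbind(keep, hr + 1L)  # matrix index (row, column = hour + 1)
  idx <- (flat[, 2L] - 1L) * n + flat[, 1L]
  hourly <- data.frame(
    admission_id = admission_id[keep], hour = hr,
    vt = vt[idx], rr = rr[idx], peep = peep[idx], p_peak = p_peak[idx],
    fio2 = fio2[idx], spo2 = spo2[idx], pao2 = pao2[idx], paco2 = paco2[idx],
    ph = ph[idx], wbc = wbc[idx], temperature = temperature[idx],
    map = map[idx], mode_spontaneous = as.integer(mode_spont[idx]),
    stringsAsFactors = FALSE)

  cohort <- structure(list(
    admissions = admissions, hourly = hourly,
    truth = list(true_ate_vfd = config$true_ate_vfd,
                 true_cate_map = config$true_cate_map,
                 true_pf_effect = config$true_pf_effect,
                 mp_threshold_true = config$mp_threshold_true,
                 true_vfd_step = config$true_vfd_step,
                 nonlinear_confounding = config$nonlinear_confounding,
                 confounders = c("age_band", "admission_type",
                                 "diagnosis_group", "apache_ii")),
    config = config, seed_used = config$seed), class = "synthetic_cohort")
  if (config$missing_rate > 0) {
    cohort <- inject_missingness(cohort, config$missing_rate,
                                 derive_seed(config$seed, 4L))
  }
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$admissions), "admissions,",
      nrow(x$hourly), "hourly rows (seed", x$seed_used, ")\n")
  cat("  true ATE (VFD28, days per J/min):", x$truth$true_ate_vfd, "\n")
  cat("  P/F hinge", x$truth$true_pf_effect, "per J/min above MP >",
      x$truth$mp_threshold_true, "J/min\n")
  invisible(x)
}

#' Knock out ventilator fields at random
#'
#' Sets each of the four MP inputs (`vt`, `rr`, `peep`, `p_peak`)
#' independently to `NA` with probability `rate`, emulating the incomplete
#' records that inclusion filtering must drop. Truth parameters are
#' untouched. Deterministic given `seed`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param rate Missingness probability in \[0, 1).
#' @param seed Integer seed.
#' @return The modified `synthetic_cohort`.
#' @export
inject_missingness <- function(cohort, rate, seed) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    stop("inject_missingness: rate must lie in [0, 1)", call. = FALSE)
  }
  if (rate == 0) return(cohort)
  set.seed(as.integer(seed))
  h <- cohort$hourly
  for (f in c("vt", "rr", "peep", "p_peak")) {
    h[[f]][stats::runif(nrow(h)) < rate] <- NA_real_
  }
  cohort$hourly <- h
  cohort
}

#' Write a synthetic cohort to the standard CSV schemas
#'
#' Emits `hourly.csv` (external schema: `vt_ml` in millilitres), an
#' `admissions.csv` and a plain-text `truth.txt` sidecar (`key=value`)
#' recording the effect parameters and seed.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hp <- file.path(dir, "hourly.csv")
  ap <- file.path(dir, "admissions.csv")
  tp <- file.path(dir, "truth.txt")
  write_hourly_csv(cohort$hourly, hp)
  write_admissions_csv(cohort$admissions, ap)
  tr <- cohort$truth
  cate <- if (is.null(tr$true_cate_map)) "" else {
    paste(sprintf("%s:%g", names(tr$true_cate_map), tr$true_cate_map),
          collapse = ",")
  }
  writeLines(c(
    sprintf("true_ate_vfd=%g", tr$true_ate_vfd),
    sprintf("true_cate_map=%s", cate),
    sprintf("true_pf_effect=%g", tr$true_pf_effect),
    sprintf("mp_threshold_true=%g", tr$mp_threshold_true),
    sprintf("true_vfd_step=%g", tr$true_vfd_step),
    sprintf("nonlinear_confounding=%s", tr$nonlinear_confounding),
    sprintf("seed=%d", cohort$seed_used)), tp)
  invisible(c(hourly = hp, admissions = ap, truth = tp))
}
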