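# Shared synthetic cohorts, generated once per test run and cached.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cohort_cache)) {
    assign(key, force(expr), envir = .cohort_cache)
  }
  get(key, envir = .cohort_cache)
}

# Default linear cohort, analysis-ready.
std_cohort <- function() {
  cached("std", {
    co <- generate_cohort(sim_config(n_admissions = 3000, seed = 424,
                                     max_hours = 24))
    inc <- apply_inclusion(co$admissions, co$hourly)
    list(cohort = co, inc = inc,
         at = analysis_table(inc$admissions, inc$hourly))
  })
}

# Cohort with long stays for grid fitting.
grid_cohort <- function() {
  cached("grid", {
    co <- generate_cohort(sim_config(n_admissions = 1200, seed = 77,
                                     max_hours = 30))
    inc <- apply_inclusion(co$admissions, co$hourly)
    list(cohort = co, inc = inc)
  })
}

# Tiny hand-built hourly/admission fixture: 5 admissions, one lacking all MP
# fields, one entirely spontaneous-mode.
toy_tables <- function() {
  mk_hours <- function(id, n = 3, spont = 0L, na_mp = FALSE) {
    data.frame(admission_id = id, hour = seq_len(n) - 1L,
               vt = if (na_mp) NA_real_ else 0.5, rr = if (na_mp) NA_real_ else 15,
               peep = if (na_mp) NA_real_ else 5,
               p_peak = if (na_mp) NA_real_ else 20,
               fio2 = 0.4, spo2 = 97, pao2 = 100, paco2 = 40, ph = 7.4,
               wbc = 10, temperature = 36.5, map = 75,
               mode_spontaneous = spont, stringsAsFactors = FALSE)
  }
  hourly <- rbind(mk_hours("a1"), mk_hours("a2"), mk_hours("a3"),
                  mk_hours("a4", na_mp = TRUE), mk_hours("a5", spont = 1L))
  admissions <- data.frame(
    admission_id = paste0("a", 1:5),
    age_band = c("60-69", "40-49", "70-79", "50-59", "80+"),
    admission_type = c("medical", "surgical", "medical", "surgical", "medical"),
    diagnosis_group = c("shock", "cardiothoracic_surgery", "infection",
                        "trauma", "respiratory_failure"),
    apache_ii = c(20, 15, 25, 12, 30),
    intubation_duration_hours = c(72, 48, 240, 96, 120),
    death_day = c(NA, NA, NA, NA, 10), stringsAsFactors = FALSE)
  list(admissions = admissions, hourly = hourly)
}
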