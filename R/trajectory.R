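# Counterfactual MP-trajectory simulation over a fitted CATE surface:
# follow the per-hour optimal MP, with i.i.d. random perturbations emulating
# unexpected clinical events (the surface itself stays fixed; the trajectory
# never feeds back into re-estimation).

#' Configuration for a trajectory simulation
#'
#' @param initial_mp Starting MP in J/min (snapped to the grid's threshold
#'   axis if off-grid, with a message).
#' @param noise_level Per-hour perturbation probability in \[0, 1\]; a level
#'   of 0.4 means 40% of hours (after hour 0) are expected to deviate from
#'   the ideal path.
#' @param horizon_hours Number of hours simulated (>= 1).
#' @param perturbation_range `(low, high)` J/min bounds for the uniform
#'   replacement draw when a perturbation fires; default `c(5, 40)`.
#' @param seed Integer seed.
#' @return Object of class `trajectory_config`.
#' @export
trajectory_config <- function(initial_mp, noise_level, horizon_hours,
                              perturbation_range = c(5, 40), seed = 1L) {
  if (noise_level < 0 || noise_level > 1) {
    stop("trajectory_config: noise_level must lie in [0, 1]", call. = FALSE)
  }
  if (horizon_hours < 1) {
    stop("trajectory_config: horizon_hours must be >= 1", call. = FALSE)
  }
  if (length(perturbation_range) != 2L ||
      perturbation_range[1L] > perturbation_range[2L]) {
    stop("trajectory_config: perturbation_range must be (low, high) with low <= high",
         call. = FALSE)
  }
  structure(list(initial_mp = initial_mp, noise_level = noise_level,
                 horizon_hours = as.integer(horizon_hours),
                 perturbation_range = perturbation_range,
                 seed = as.integer(seed)),
            class = "trajectory_config")
}

#' Simulate a counterfactual MP trajectory over a CATE surface
#'
#' Hour 0 realises the configured initial MP (snapped to the grid axis). For
#' every subsequent hour the ideal MP is the [optimal_threshold_path()] value
#' for that hour; with probability `noise_level` the realised value is instead
#' a uniform draw within `perturbation_range`, snapped to the grid axis.
#' Hours whose path value is undefined (fully masked) carry the previous
#' ideal value forward with a warning. The effect value of the surface at the
#' realised MP is recorded per hour. Deterministic given the seed; two runs
#' differing only in seed differ only at perturbed hours.
#'
#' @param grid A [cate_grid()] covering the horizon.
#' @param config A [trajectory_config()].
#' @return Object of class `trajectory_result`: data frame `path` with
#'   columns `hour`, `ideal_mp`, `realized_mp`, `was_perturbed`,
#'   `cate_at_realized`, plus the config echo and seed.
#' @export
simulate_trajectory <- function(grid, config) {
  stopifnot(inherits(grid, "cate_grid"), inherits(config, "trajectory_config"))
  H <- config$horizon_hours
  if (H > length(grid$hours)) {
    stop("simulate_trajectory: horizon (", H, " h) exceeds the grid's ",
         length(grid$hours), " hours", call. = FALSE)
  }
  th <- grid$thresholds
  snap <- function(x) th[which.min(abs(th - x))]
  init <- snap(config$initial_mp)
  if (init != config$initial_mp) {
    message("initial_mp ", config$initial_mp, " snapped to grid value ", init)
  }
  opt <- optimal_threshold_path(grid)
  set.seed(derive_seed(config$seed, 31L))
  u_flag <- stats::runif(H)
  u_val <- stats::runif(H, config$perturbation_range[1L],
                        config$perturbation_range[2L])
  perturbed <- u_flag < config$noise_level
  perturbed[1L] <- FALSE                     # hour 0 realises the initial MP

  ideal <- numeric(H)
  realized <- numeric(H)
  ideal[1L] <- init
  realized[1L] <- init
  for (k in seq_len(H)[-1L]) {
    ide <- opt[k]
    if (is.na(ide)) {
      warning("undefined optimal path at hour ", grid$hours[k],
              "; carrying previous ideal MP forward", call. = FALSE)
      ide <- ideal[k - 1L]
    }
    ideal[k] <- ide
    realized[k] <- if (perturbed[k]) snap(u_val[k]) else ide
  }
  jj <- match(realized, th)
  cate <- grid$estimates[cbind(seq_len(H), jj)]
  path <- data.frame(hour = grid$hours[seq_len(H)], ideal_mp = ideal,
                     realized_mp = realized, was_perturbed = perturbed,
                     cate_at_realized = cate)
  structure(list(path = path, config = config, seed = config$seed,
                 cohort = grid$cohort),
            class = "trajectory_result")
}

#' @export
print.trajectory_result <- function(x, ...) {
  r <- trajectory_report(x)
  cat(sprintf("trajectory_result [%s]: %d hours, %d perturbed (%.1f%%), cumulative effect %.3f\n",
              x$cohort, r$n_hours, r$n_perturbed, 100 * r$fraction_perturbed,
              r$cumulative_cate))
  invisible(x)
}

#' Summarise a simulated trajectory
#'
#' @param result A [simulate_trajectory()] result.
#' @return List: `cumulative_cate` (sum of the surface values along the
#'   realised path, `NA` cells skipped with a count), `n_hours`,
#'   `n_perturbed` and `fraction_perturbed` (hour 0 is excluded from the
#'   denominator since it can never be perturbed), and the per-hour `table`
#'   suitable for heatmap overlays (ideal = white, perturbed = red in the
#'   conventional rendering).
#' @export
trajectory_report <- function(result) {
  stopifnot(inherits(result, "trajectory_result"))
  p <- result$path
  if (nrow(p) == 0L) stop("trajectory_report: empty result", call. = FALSE)
  eligible <- if (nrow(p) > 1L) p$was_perturbed[-1L] else logical(0)
  list(
    cumulative_cate = sum(p$cate_at_realized, na.rm = TRUE),
    n_missing_cate = sum(is.na(p$cate_at_realized)),
    n_hours = nrow(p),
    n_perturbed = sum(p$was_perturbed),
    fraction_perturbed = if (length(eligible)) mean(eligible) else 0,
    table = p)
}

#' Export trajectory results
#'
#' `write_trajectory_csv()` writes the per-hour table;
#' `write_trajectory_summary()` a plain-text `key=value` summary;
#' `trajectory_plot_data()` returns (optionally writes) a JSON payload with
#' the surface and path markers for heatmap-overlay plotting.
#'
#' @param result A `trajectory_result`.
#' @param path Output file path.
#' @export
write_trajectory_csv <- function(result, path) {
  utils::write.csv(format(result$path, digits = 10, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
write_trajectory_summary <- function(result, path) {
  r <- trajectory_report(result)
  writeLines(c(
    sprintf("cohort=%s", result$cohort),
    sprintf("cumulative_cate=%.10g", r$cumulative_cate),
    sprintf("n_hours=%d", r$n_hours),
    sprintf("n_perturbed=%d", r$n_perturbed),
    sprintf("fraction_perturbed=%.10g", r$fraction_perturbed),
    sprintf("noise_level=%g", result$config$noise_level),
    sprintf("initial_mp=%g", result$config$initial_mp),
    sprintf("seed=%d", result$seed)), path)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param grid The `cate_grid` the trajectory was simulated on.
#' @export
trajectory_plot_data <- function(result, grid, path = NULL) {
  long <- expand.grid(hour = grid$hours, threshold = grid$thresholds,
                      KEEP.OUT.ATTRS = FALSE)
  long$estimate <- grid$estimates[cbind(match(long$hour, grid$hours),
                                        match(long$threshold,
                                              grid$thresholds))]
  payload <- list(surface = long, path = result$path,
                  legend = list(ideal = "white", perturbed = "red"))
  if (!is.null(path)) {
    jsonlite::write_json(payload, path, dataframe = "columns",
                         auto_unbox = TRUE, digits = NA, na = "null")
    return(invisible(path))
  }
  payload
}
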