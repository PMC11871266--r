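# Treatment-effect estimators: backdoor linear regression (OLS treatment
# coefficient solved by QR, not delegated to lm()) and double machine
# learning by cross-fitted partialling-out, plus subgroup CATEs and
# binary-threshold recoding.

#' Construct an effect estimate
#'
#' Container for a single ATE or CATE with its confidence interval and
#' provenance (estimator, treatment coding, subgroup, adjustment set).
#'
#' @param estimand `"ATE"` or `"CATE"`.
#' @param estimator_tag e.g. `"backdoor_lr"`, `"dml_forest"`, `"dml_generic"`.
#' @param treatment_var,outcome_var Column names.
#' @param treatment_coding `"continuous"` or `"binary_threshold(<theta>)"`.
#' @param subgroup Cohort label or `"all"`.
#' @param point,ci_low,ci_high,se Effect and nominal 95% CI (days per J/min
#'   for continuous VFD28 effects; days for binary coding; P/F units for
#'   oxygenation models).
#' @param n Number of admissions used.
#' @param adjustment Character vector of adjustment variables.
#' @param suppressed `TRUE` when the cell was below the minimum size and no
#'   estimate was computed.
#' @param extra Named list of additional fields (kept on the object).
#' @return Object of class `effect_estimate`.
#' @export
effect_estimate <- function(estimand, estimator_tag, treatment_var,
                            treatment_coding, outcome_var, subgroup,
                            point, ci_low, ci_high, se, n, adjustment,
                            suppressed = FALSE, extra = list()) {
  if (!suppressed && !is.na(point)) {
    if (!(ci_low <= point && point <= ci_high)) {
      stop("effect_estimate: CI must bracket the point estimate",
           call. = FALSE)
    }
  }
  structure(c(list(estimand = estimand, estimator_tag = estimator_tag,
                   treatment_var = treatment_var,
                   treatment_coding = treatment_coding,
                   outcome_var = outcome_var, subgroup = subgroup,
                   point = point, ci_low = ci_low, ci_high = ci_high,
                   se = se, n = n, adjustment = adjustment,
                   suppressed = suppressed), extra),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  if (isTRUE(x$suppressed)) {
    cat(sprintf("%s [%s] %s: suppressed (n = %d below minimum)\n",
                x$estimand, x$estimator_tag, x$subgroup, x$n))
    return(invisible(x))
  }
  cat(sprintf("%s [%s] of %s (%s) on %s, subgroup %s:\n", x$estimand,
              x$estimator_tag, x$treatment_var, x$treatment_coding,
              x$outcome_var, x$subgroup))
  cat(sprintf("  %.4f (95%% CI %.4f to %.4f), n = %d\n", x$point, x$ci_low,
              x$ci_high, x$n))
  invisible(x)
}

#' @export
as.data.frame.effect_estimate <- function(x, ...) {
  data.frame(estimand = x$estimand, estimator_tag = x$estimator_tag,
             treatment_var = x$treatment_var,
             treatment_coding = x$treatment_coding,
             outcome_var = x$outcome_var, subgroup = x$subgroup,
             point = x$point, ci_low = x$ci_low, ci_high = x$ci_high,
             se = x$se, n = x$n,
             adjustment_set = paste(x$adjustment, collapse = ";"),
             suppressed = x$suppressed, stringsAsFactors = FALSE)
}

#' Write effect estimates as a tidy CSV
#'
#' One row per estimate, stable column order: estimand, estimator_tag,
#' treatment_var, treatment_coding, outcome_var, subgroup, point, ci_low,
#' ci_high, se, n, adjustment_set, suppressed.
#'
#' @param estimates A single `effect_estimate` or a list of them.
#' @param path Output CSV path.
#' @return Invisibly, the combined data frame.
#' @export
write_estimates_csv <- function(estimates, path) {
  df <- estimates_table(estimates)
  utils::write.csv(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(df)
}

#' @rdname write_estimates_csv
#' @export
estimates_table <- function(estimates) {
  if (inherits(estimates, "effect_estimate")) estimates <- list(estimates)
  do.call(rbind, lapply(estimates, as.data.frame))
}

adjustment_vars <- function(adjustment) {
  if (inherits(adjustment, "adjustment_set")) return(adjustment$variables)
  if (inherits(adjustment, "adjustment_sets")) return(adjustment[[1L]]$variables)
  as.character(adjustment)
}

# Drop adjustment variables that are constant in `data` (e.g. admission_type
# inside a single-arm subgroup); they carry no information and break the
# full-rank requirement.
drop_constant_vars <- function(data, vars) {
  keep <- vapply(vars, function(v) length(unique(data[[v]])) > 1L, TRUE)
  vars[keep]
}

# Design matrix with intercept; characters become factor dummies.
adjustment_design <- function(data, vars) {
  if (!length(vars)) {
    return(matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)")))
  }
  df <- data[vars]
  for (v in vars) if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  stats::model.matrix(stats::reformulate(vars), data = df)
}

# OLS treatment coefficient by QR factorisation of [X, t]. Errors on rank
# deficiency, naming the offending columns; with drop_aliased = TRUE,
# aliased adjustment columns are dropped instead (the treatment itself must
# always be identified).
ols_treatment_coef <- function(y, t, X, label = "treatment",
                               drop_aliased = FALSE) {
  M <- cbind(X, t)
  colnames(M)[ncol(M)] <- label
  qr_m <- qr(M)
  if (qr_m$rank < ncol(M)) {
    bad <- colnames(M)[qr_m$pivot[(qr_m$rank + 1L):ncol(M)]]
    if (!drop_aliased || label %in% bad) {
      stop("rank-deficient design; collinear column(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    M <- M[, qr_m$pivot[seq_len(qr_m$rank)], drop = FALSE]
    qr_m <- qr(M)
  }
  beta <- qr.coef(qr_m, y)
  unname(beta[label])
}

#' Backdoor-adjusted linear ATE
#'
#' Point estimate is the treatment coefficient of the least-squares fit of
#' `outcome` on `treatment` plus the adjustment variables, solved by QR
#' factorisation of the design matrix. The confidence interval is a
#' percentile interval from an admission-level nonparametric bootstrap
#' (admissions are the independent units).
#'
#' @param data Admission-level analysis table.
#' @param treatment,outcome Column names (numeric).
#' @param adjustment Character vector of adjustment columns, or an
#'   `adjustment_set`. Constant columns are dropped.
#' @param n_boot Bootstrap resamples (default 500).
#' @param conf_level Nominal CI level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @param subgroup Label recorded on the estimate (default `"all"`).
#' @param estimand Recorded estimand tag.
#' @param drop_aliased Drop exactly aliased adjustment columns (e.g. a
#'   diagnosis level that determines the admission arm in a small cohort)
#'   instead of failing; rank deficiency involving the treatment itself
#'   always errors. Default `FALSE` (strict).
#' @return An [effect_estimate()] with `estimator_tag = "backdoor_lr"`.
#' @export
backdoor_linear_ate <- function(data, treatment, outcome, adjustment,
                                n_boot = 500, conf_level = 0.95, seed = 1L,
                                subgroup = "all", estimand = "ATE",
                                drop_aliased = FALSE) {
  vars <- drop_constant_vars(data, adjustment_vars(adjustment))
  cc <- stats::complete.cases(data[c(treatment, outcome, vars)])
  data <- data[cc, , drop = FALSE]
  n <- nrow(data)
  X <- adjustment_design(data, vars)
  if (n <= ncol(X) + 2L) {
    stop("backdoor_linear_ate: too few observations (n = ", n,
         ") for ", ncol(X) + 1L, " coefficients", call. = FALSE)
  }
  y <- data[[outcome]]
  t <- data[[treatment]]
  point <- ols_treatment_coef(y, t, X, treatment, drop_aliased)
  set.seed(derive_seed(seed, 21L))
  boot <- vapply(seq_len(n_boot), function(b) {
    ix <- sample.int(n, n, replace = TRUE)
    tryCatch(ols_treatment_coef(y[ix], t[ix], X[ix, , drop = FALSE],
                                treatment, drop_aliased = TRUE),
             error = function(e) NA_real_)
  }, numeric(1))
  boot <- boot[!is.na(boot)]
  alpha <- (1 - conf_level) / 2
  qs <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE, type = 7)
  effect_estimate(
    estimand = estimand, estimator_tag = "backdoor_lr",
    treatment_var = treatment, treatment_coding = "continuous",
    outcome_var = outcome, subgroup = subgroup,
    point = point, ci_low = min(qs[1L], point), ci_high = max(qs[2L], point),
    se = stats::sd(boot), n = n, adjustment = vars)
}

# Cross-fitted out-of-fold predictions of `y` from covariates.
# learner_kind "forest" uses ranger; "generic" a linear ridge-free OLS fit;
# a custom `learner(train_df, y_train)` returning `function(new_df)` wins.
crossfit_predict <- function(df, y, folds, learner_kind, seed,
                             num_trees = 200, learner = NULL) {
  pred <- numeric(length(y))
  for (k in sort(unique(folds))) {
    test <- folds == k
    train <- !test
    if (!is.null(learner)) {
      fit <- learner(df[train, , drop = FALSE], y[train])
      pred[test] <- fit(df[test, , drop = FALSE])
    } else if (learner_kind == "forest") {
      tr <- df[train, , drop = FALSE]
      tr$.y <- y[train]
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = tr, num.trees = num_trees,
        min.node.size = 5, seed = derive_seed(seed, 100L + k),
        num.threads = 1, respect.unordered.factors = "order")
      pred[test] <- stats::predict(fit, df[test, , drop = FALSE],
                                   num.threads = 1)$predictions
    } else {
      X <- adjustment_design(rbind(df[train, , drop = FALSE],
                                   df[test, , drop = FALSE]), names(df))
      ntr <- sum(train)
      Xtr <- X[seq_len(ntr), , drop = FALSE]
      qr_x <- qr(Xtr)
      beta <- qr.coef(qr_x, y[train])
      beta[is.na(beta)] <- 0
      pred[test] <- X[-seq_len(ntr), , drop = FALSE] %*% beta
    }
  }
  pred
}

#' Double machine learning ATE (cross-fitted partialling-out)
#'
#' Admissions are split into `k_folds` folds; on each held-out fold the
#' outcome and the treatment are predicted from the adjustment variables by
#' models fit on the remaining folds. The effect is the residual-on-residual
#' slope over out-of-fold residuals,
#' \deqn{\hat\theta = \sum \tilde r_T \tilde r_Y / \sum \tilde r_T^2,}
#' the Neyman-orthogonal partialling-out score. Two interval constructions
#' are reported: the influence-function (sandwich) variance, and an
#' admission-level bootstrap of the residual pairs; `ci_method` selects which
#' one populates `ci_low`/`ci_high` (the other is kept in the extra fields).
#'
#' @inheritParams backdoor_linear_ate
#' @param learner_kind `"forest"` (ranger tree ensembles) or `"generic"`
#'   (linear least-squares nuisances, or a custom `learner`).
#' @param k_folds Cross-fitting folds (>= 2, default 5).
#' @param num_trees Trees per forest nuisance fit (default 200).
#' @param learner Optional custom nuisance learner:
#'   `function(train_df, y) -> function(new_df) predictions`.
#' @param ci_method `"influence"` (default) or `"bootstrap"`.
#' @return An [effect_estimate()] tagged `dml_forest` or `dml_generic`, with
#'   extra fields `se_influence`, `boot_ci_low`, `boot_ci_high`.
#' @export
dml_ate <- function(data, treatment, outcome, adjustment,
                    learner_kind = c("forest", "generic"), k_folds = 5,
                    seed = 1L, n_boot = 500, conf_level = 0.95,
                    num_trees = 200, learner = NULL,
                    ci_method = c("influence", "bootstrap"),
                    subgroup = "all", estimand = "ATE") {
  learner_kind <- match.arg(learner_kind)
  ci_method <- match.arg(ci_method)
  if (k_folds < 2L) stop("dml_ate: k_folds must be >= 2", call. = FALSE)
  vars <- drop_constant_vars(data, adjustment_vars(adjustment))
  cc <- stats::complete.cases(data[c(treatment, outcome, vars)])
  data <- data[cc, , drop = FALSE]
  n <- nrow(data)
  if (n < 4L * k_folds) {
    stop("dml_ate: too few observations for ", k_folds, " folds", call. = FALSE)
  }
  df <- data[vars]
  for (v in vars) if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  y <- data[[outcome]]
  t <- data[[treatment]]
  set.seed(derive_seed(seed, 11L))
  folds <- sample(rep_len(seq_len(k_folds), n))
  y_hat <- crossfit_predict(df, y, folds, learner_kind, seed,
                            num_trees, learner)
  t_hat <- crossfit_predict(df, t, folds, learner_kind, derive_seed(seed, 1L),
                            num_trees, learner)
  rt <- t - t_hat
  ry <- y - y_hat
  denom <- sum(rt^2)
  if (denom / n < 1e-10 * max(stats::var(t), 1e-12) || denom == 0) {
    stop("dml_ate: no overlap/variation - treatment residual variance ~ 0 ",
         "(treatment fully explained by confounders)", call. = FALSE)
  }
  theta <- sum(rt * ry) / denom
  psi <- rt * (ry - theta * rt)
  se_if <- sqrt(sum(psi^2) / n) / (denom / n) / sqrt(n)
  set.seed(derive_seed(seed, 12L))
  boot <- vapply(seq_len(n_boot), function(b) {
    ix <- sample.int(n, n, replace = TRUE)
    d <- sum(rt[ix]^2)
    if (d == 0) return(NA_real_)
    sum(rt[ix] * ry[ix]) / d
  }, numeric(1))
  boot <- boot[!is.na(boot)]
  alpha <- (1 - conf_level) / 2
  z <- stats::qnorm(1 - alpha)
  bq <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE, type = 7)
  if (ci_method == "influence") {
    ci <- c(theta - z * se_if, theta + z * se_if)
  } else {
    ci <- c(min(bq[1L], theta), max(bq[2L], theta))
  }
  effect_estimate(
    estimand = estimand,
    estimator_tag = paste0("dml_", learner_kind),
    treatment_var = treatment, treatment_coding = "continuous",
    outcome_var = outcome, subgroup = subgroup,
    point = theta, ci_low = ci[1L], ci_high = ci[2L],
    se = if (ci_method == "influence") se_if else stats::sd(boot),
    n = n, adjustment = vars,
    extra = list(se_influence = se_if, se_boot = stats::sd(boot),
                 boot_ci_low = bq[1L], boot_ci_high = bq[2L],
                 k_folds = k_folds))
}

run_estimator <- function(estimator, data, treatment, outcome, adjustment,
                          seed, subgroup = "all", estimand = "ATE", ...) {
  dots <- list(...)
  switch(estimator,
    backdoor_lr = backdoor_linear_ate(
      data, treatment, outcome, adjustment, seed = seed,
      subgroup = subgroup, estimand = estimand,
      n_boot = dots$n_boot %||% 500,
      drop_aliased = dots$drop_aliased %||% FALSE),
    dml_forest = dml_ate(
      data, treatment, outcome, adjustment, learner_kind = "forest",
      seed = seed, subgroup = subgroup, estimand = estimand,
      k_folds = dots$k_folds %||% 5, n_boot = dots$n_boot %||% 500,
      num_trees = dots$num_trees %||% 200),
    dml_generic = dml_ate(
      data, treatment, outcome, adjustment, learner_kind = "generic",
      seed = seed, subgroup = subgroup, estimand = estimand,
      k_folds = dots$k_folds %||% 5, n_boot = dots$n_boot %||% 500,
      learner = dots$learner),
    stop("unknown estimator tag: ", estimator, call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Subgroup CATEs
#'
#' Applies the configured estimator within each level of a grouping column.
#' Groups below the minimum size are reported as suppressed rows rather than
#' estimated. The same seed is passed to every subgroup fit, so a grouping
#' with a single level reproduces the corresponding ATE call exactly.
#'
#' @inheritParams backdoor_linear_ate
#' @param grouping Name of the cohort-label column.
#' @param estimator `"backdoor_lr"`, `"dml_forest"` or `"dml_generic"`.
#' @param min_n Minimum admissions per subgroup (default 50).
#' @param ... Passed to the estimator (e.g. `n_boot`, `k_folds`).
#' @return List of [effect_estimate()]s (class `effect_estimate_list`).
#' @export
cate_by_subgroup <- function(data, grouping, treatment, outcome, adjustment,
                             estimator = "backdoor_lr", min_n = 50,
                             seed = 1L, ...) {
  if (!grouping %in% names(data)) {
    stop("cate_by_subgroup: unknown grouping column: ", grouping,
         call. = FALSE)
  }
  vars <- setdiff(adjustment_vars(adjustment), grouping)
  levels <- sort(unique(data[[grouping]]))
  out <- lapply(levels, function(g) {
    sub <- data[data[[grouping]] == g, , drop = FALSE]
    if (nrow(sub) < min_n) {
      return(effect_estimate(
        estimand = "CATE", estimator_tag = estimator,
        treatment_var = treatment, treatment_coding = "continuous",
        outcome_var = outcome, subgroup = as.character(g),
        point = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        se = NA_real_, n = nrow(sub), adjustment = vars, suppressed = TRUE))
    }
    run_estimator(estimator, sub, treatment, outcome, vars, seed = seed,
                  subgroup = as.character(g), estimand = "CATE", ...)
  })
  structure(out, class = "effect_estimate_list")
}

#' @export
print.effect_estimate_list <- function(x, ...) {
  for (e in x) print(e)
  invisible(x)
}

#' Effect of exceeding an MP threshold
#'
#' Recodes the treatment as the indicator `1{treatment > theta}` and
#' estimates its effect with the configured estimator; the coding is recorded
#' on the returned estimate. Thresholds leaving either arm empty (or below
#' the minimum arm size) raise a classed `ventcausal_degenerate_threshold`
#' error.
#'
#' @inheritParams cate_by_subgroup
#' @param threshold MP threshold theta in J/min.
#' @param min_arm_n Minimum admissions per arm (default 50).
#' @return An [effect_estimate()] with binary treatment coding (effect in
#'   outcome units, e.g. days).
#' @export
binary_effect_at_threshold <- function(data, threshold, treatment, outcome,
                                       adjustment, estimator = "backdoor_lr",
                                       min_arm_n = 50, seed = 1L, ...) {
  tr <- as.numeric(data[[treatment]] > threshold)
  n1 <- sum(tr == 1, na.rm = TRUE)
  n0 <- sum(tr == 0, na.rm = TRUE)
  if (n1 < min_arm_n || n0 < min_arm_n) {
    stop(structure(class = c("ventcausal_degenerate_threshold", "error",
                             "condition"),
                   list(message = sprintf(
                     "degenerate threshold %g: arm sizes %d (above) / %d (below) under minimum %d",
                     threshold, n1, n0, min_arm_n), call = NULL)))
  }
  d2 <- data
  d2$.treated <- tr
  est <- run_estimator(estimator, d2, ".treated", outcome,
                       adjustment_vars(adjustment), seed = seed, ...)
  est$treatment_var <- treatment
  est$treatment_coding <- sprintf("binary_threshold(%g)", threshold)
  est
}
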