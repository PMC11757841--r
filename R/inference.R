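#' Z-score selected predictor columns
#'
#' Named columns are centred and scaled with the sample mean and sd (n-1
#' denominator); scaling constants are recorded in the `"scaling"` attribute
#' for reporting back on the raw scale.
#'
#' @param data A data frame.
#' @param vars Character vector of numeric column names to scale.
#' @return `data` with the named columns z-scored.
#' @export
scale_predictors <- function(data, vars) {
  stopifnot(is.data.frame(data), all(vars %in% names(data)))
  scaling <- data.frame(variable = vars, center = NA_real_, sd = NA_real_)
  for (i in seq_along(vars)) {
    x <- data[[vars[i]]]
    if (!is.numeric(x)) stop("Column `", vars[i], "` is not numeric.")
    s <- stats::sd(x)
    if (is.na(s) || s == 0) {
      stop("Column `", vars[i], "` has zero variance; cannot standardize.")
    }
    scaling$center[i] <- mean(x)
    scaling$sd[i] <- s
    data[[vars[i]]] <- (x - mean(x)) / s
  }
  attr(data, "scaling") <- scaling
  data
}

#' Default model terms of the booster-willingness regression
#'
#' `default_predictors()` names the eight fixed effects;
#' `default_scaled()` the subset z-scored before fitting.
#'
#' @return A character vector of cohort column names.
#' @export
default_predictors <- function() {
  c("age", "gender", "education", "relative_income", "essential",
    "distress", "ius12_total", "auc")
}

#' @rdname default_predictors
#' @export
default_scaled <- function() {
  c("age", "relative_income", "distress", "ius12_total")
}

#' Fit the country-nested random-intercept logistic model
#'
#' Booster willingness (0/1) is regressed on the participant-level predictors
#' with one Gaussian random intercept per country, maximizing the marginal
#' likelihood via `lme4::glmer` (Laplace approximation by default; adaptive
#' Gauss-Hermite quadrature with `nAGQ > 1`). Rows with a missing value in
#' any model column are dropped listwise before fitting. Fixed effects are
#' reported as log-odds with Wald z-tests, odds ratios and 95\% Wald
#' intervals `exp(b +/- 1.96 SE)`.
#'
#' @param data Cohort data frame (e.g. `generate_cohort()$cohort`).
#' @param outcome Name of the 0/1 outcome column.
#' @param group Name of the grouping (country) column.
#' @param predictors Fixed-effect column names; default the study's eight
#'   predictors. `NULL` fits the intercept-only (null) model.
#' @param scale_vars Subset of `predictors` to z-score before fitting
#'   (default: age, relative income, distress, intolerance of uncertainty).
#' @param nAGQ Number of adaptive Gauss-Hermite quadrature points (1 =
#'   Laplace).
#' @param control A `lme4::glmerControl`; the default uses bobyqa with a
#'   tight convergence tolerance.
#' @return A `booster_fit` object: coefficient table (`b`, `se`, `z`, `p`,
#'   `or`, `ci_low`, `ci_high`), random-intercept variance and SD,
#'   log-likelihood, sizes, method, and the underlying `glmerMod`.
#' @export
fit_booster_glmm <- function(data, outcome = "booster_willing",
                             group = "country",
                             predictors = default_predictors(),
                             scale_vars = default_scaled(),
                             nAGQ = 1L,
                             control = lme4::glmerControl(
                               optimizer = "bobyqa",
                               optCtrl = list(rhobeg = 0.2, rhoend = 2e-9))) {
  cols <- c(outcome, group, predictors)
  stopifnot(is.data.frame(data), all(cols %in% names(data)))
  data <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
               drop = FALSE]
  y <- data[[outcome]]
  if (!all(y %in% c(0, 1))) stop("`", outcome, "` must be binary 0/1.")
  if (length(unique(data[[group]])) < 2L) {
    stop("At least 2 groups are required for a random intercept.")
  }
  scaling <- NULL
  if (length(scale_vars)) {
    stopifnot(all(scale_vars %in% predictors))
    data <- scale_predictors(data, scale_vars)
    scaling <- attr(data, "scaling")
  }
  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  fml <- stats::as.formula(paste0(outcome, " ~ ", rhs, " + (1 | ", group, ")"))
  fit <- lme4::glmer(fml, data = data, family = stats::binomial(),
                     nAGQ = nAGQ, control = control)
  co <- summary(fit)$coefficients
  coefs <- data.frame(
    term = rownames(co),
    b = co[, "Estimate"],
    se = co[, "Std. Error"],
    z = co[, "z value"],
    p = co[, "Pr(>|z|)"],
    row.names = NULL
  )
  coefs$or <- exp(coefs$b)
  coefs$ci_low <- exp(coefs$b - 1.96 * coefs$se)
  coefs$ci_high <- exp(coefs$b + 1.96 * coefs$se)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_u <- vc$vcov[1L]
  msgs <- fit@optinfo$conv$lme4$messages
  structure(
    list(coefficients = coefs,
         intercept_variance = var_u,
         intercept_sd = sqrt(var_u),
         log_likelihood = as.numeric(stats::logLik(fit)),
         n_obs = nrow(data),
         n_groups = length(unique(data[[group]])),
         n_fixed = nrow(coefs),
         method = if (nAGQ > 1) paste0("adaptive Gauss-Hermite (", nAGQ,
                                       " nodes)") else "Laplace",
         converged = is.null(msgs),
         messages = msgs,
         scaling = scaling,
         formula = fml,
         model = fit),
    class = "booster_fit"
  )
}

#' @export
print.booster_fit <- function(x, digits = 3, ...) {
  cat("Multilevel logistic regression (", x$method, ")\n", sep = "")
  cat("  n =", x$n_obs, "observations in", x$n_groups, "groups;",
      "logLik =", format(x$log_likelihood, digits = 8), "\n\n")
  tab <- x$coefficients
  tab$ci <- sprintf("[%.*f, %.*f]", digits - 1, tab$ci_low, digits - 1, tab$ci_high)
  out <- data.frame(term = tab$term,
                    b = round(tab$b, digits),
                    SE = round(tab$se, digits),
                    z = round(tab$z, digits),
                    p = signif(tab$p, digits),
                    OR = round(tab$or, digits),
                    `95% CI` = tab$ci, check.names = FALSE)
  print(out, row.names = FALSE)
  cat(sprintf("\nRandom effects: intercept variance (group) = %.*f, SD = %.*f\n",
              digits, x$intercept_variance, digits, x$intercept_sd))
  if (!x$converged) cat("Note:", paste(x$messages, collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.data.frame.booster_fit <- function(x, ...) x$coefficients

#' Likelihood-ratio test between nested fits
#'
#' The statistic is twice the log-likelihood difference; degrees of freedom
#' are the difference in fixed-effect counts (the null model retains the
#' random intercept, so the test isolates the fixed effects); the p-value is
#' the chi-square upper tail.
#'
#' @param full,null `booster_fit` objects fitted to the same rows.
#' @return A `dd_lrt` list with `statistic`, `df`, `p`.
#' @export
lrt <- function(full, null) {
  stopifnot(inherits(full, "booster_fit"), inherits(null, "booster_fit"))
  if (full$n_obs != null$n_obs) {
    stop("Models were fitted to different numbers of rows (",
         full$n_obs, " vs ", null$n_obs, "); refit on identical data.")
  }
  df <- full$n_fixed - null$n_fixed
  if (df < 0) stop("`full` has fewer fixed effects than `null`; models not nested.")
  stat <- 2 * (full$log_likelihood - null$log_likelihood)
  if (stat < -1e-6) {
    warning("Negative LRT statistic (", format(stat),
            "): check nesting/convergence.")
  }
  stat <- max(stat, 0)
  structure(list(statistic = stat, df = df,
                 p = stats::pchisq(stat, df = df, lower.tail = FALSE)),
            class = "dd_lrt")
}

#' @export
print.dd_lrt <- function(x, ...) {
  cat(sprintf("Likelihood ratio test: chi-square(%d) = %.2f, p = %.3g\n",
              x$df, x$statistic, x$p))
  invisible(x)
}

#' Mean discounting curves by outcome group
#'
#' Per-delay mean indifference point and standard error of the mean, split by
#' the binary outcome — the numeric summary behind a willing-vs-unwilling
#' discounting-curve figure.
#'
#' @param indifference Long data frame with `participant_id`, `delay_days`,
#'   `subjective_value`.
#' @param outcomes Data frame with `participant_id` and a 0/1 `outcome`
#'   column (name via `outcome`).
#' @param outcome Name of the outcome column in `outcomes`.
#' @return Data frame with `group`, `delay_days`, `n`, `mean_sv`, `se_sv`.
#' @export
group_curves <- function(indifference, outcomes, outcome = "booster_willing") {
  stopifnot(all(c("participant_id", "delay_days", "subjective_value") %in%
                  names(indifference)),
            all(c("participant_id", outcome) %in% names(outcomes)))
  merged <- merge(indifference,
                  outcomes[, c("participant_id", outcome)],
                  by = "participant_id")
  merged <- merged[!is.na(merged[[outcome]]), ]
  if (!nrow(merged)) stop("No observations with a non-missing outcome.")
  groups <- sort(unique(merged[[outcome]]))
  if (any(!table(merged[[outcome]]) > 0)) stop("Empty outcome group.")
  out <- do.call(rbind, lapply(groups, function(g) {
    sub <- merged[merged[[outcome]] == g, ]
    agg <- do.call(rbind, lapply(split(sub, sub$delay_days), function(d) {
      data.frame(group = g, delay_days = d$delay_days[1], n = nrow(d),
                 mean_sv = mean(d$subjective_value),
                 se_sv = stats::sd(d$subjective_value) / sqrt(nrow(d)))
    }))
    agg
  }))
  rownames(out) <- NULL
  out[order(out$group, out$delay_days), ]
}
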