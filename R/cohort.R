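#' Specification of a synthetic booster-willingness cohort
#'
#' Defaults reproduce the study conditions: n = 2547 participants nested in
#' 13 countries, covariate marginals matching the reported sample (age mean
#' 30.92 sd 11.42 truncated at 18; relative income mean 38.83 sd 23.8 on a
#' 0-100 scale; 22\% essential workers; 55.6\% female; education 30/49/20\%
#' secondary/undergraduate/postgraduate), the fitted fixed effects of the
#' booster-willingness model, and a country random-intercept SD of 0.41.
#' Discounting behaviour comes from hyperbolic agents with
#' `log10(k) ~ Normal(-2.2, 0.6)` (per day) run through the titration engine,
#' not from a sampled AuC.
#'
#' @param n Number of participants.
#' @param n_countries Number of countries (level-2 groups).
#' @param country_weights Sampling proportions over countries (default
#'   uniform); must sum to 1.
#' @param fixed_effects Named coefficients of the outcome model on the scale
#'   the model is fitted on: z-scored age, relative income, distress and
#'   intolerance of uncertainty; raw 0/1 gender (female = 1), 0/1/2
#'   education, 0/1 essential worker, and raw AuC in (0, 1].
#' @param intercept_sd SD of the country random intercepts.
#' @param age_mean,age_sd,age_min Age marginal (truncated normal, years).
#' @param income_mean,income_sd Relative income marginal (normal truncated
#'   to `[0, 100]`).
#' @param p_essential,p_female Bernoulli probabilities.
#' @param education_probs Proportions for secondary/undergraduate/
#'   postgraduate (coded 0/1/2); normalized to sum to 1.
#' @param k_log10_mean,k_log10_sd Normal parameters of `log10(k)` per day.
#' @param severity_shape1,severity_shape2 Beta parameters of the latent
#'   symptom-severity used to draw GAD-7/PHQ-9/IUS-12 items.
#' @param latent_cor Gaussian-copula correlation between the distress and
#'   intolerance-of-uncertainty latents.
#' @param task A [task_config()] for the discounting task.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n = 2547L, n_countries = 13L, country_weights = NULL,
                        fixed_effects = c(intercept = 0.95, age = 0.01,
                                          gender = -0.23, education = 0.02,
                                          relative_income = -0.14,
                                          essential = -0.08, distress = 0.08,
                                          ius = -0.08, auc = 0.67),
                        intercept_sd = 0.41,
                        age_mean = 30.92, age_sd = 11.42, age_min = 18,
                        income_mean = 38.83, income_sd = 23.8,
                        p_essential = 0.22, p_female = 0.556,
                        education_probs = c(secondary = 0.30,
                                            undergraduate = 0.49,
                                            postgraduate = 0.20),
                        k_log10_mean = -2.2, k_log10_sd = 0.6,
                        severity_shape1 = 2, severity_shape2 = 5,
                        latent_cor = 0.5,
                        task = task_config()) {
  n <- as.integer(n); n_countries <- as.integer(n_countries)
  stopifnot(n >= 1L, n_countries >= 1L, intercept_sd >= 0,
            age_sd > 0, income_sd > 0,
            p_essential >= 0, p_essential <= 1,
            p_female >= 0, p_female <= 1,
            k_log10_sd >= 0, abs(latent_cor) < 1)
  if (is.null(country_weights)) {
    country_weights <- rep(1 / n_countries, n_countries)
  }
  if (length(country_weights) != n_countries ||
      abs(sum(country_weights) - 1) > 1e-8 || any(country_weights < 0)) {
    stop("`country_weights` must be ", n_countries,
         " nonnegative proportions summing to 1.")
  }
  needed <- c("intercept", "age", "gender", "education", "relative_income",
              "essential", "distress", "ius", "auc")
  if (!all(needed %in% names(fixed_effects))) {
    stop("`fixed_effects` must name: ", paste(needed, collapse = ", "))
  }
  education_probs <- education_probs / sum(education_probs)
  structure(
    list(n = n, n_countries = n_countries, country_weights = country_weights,
         fixed_effects = fixed_effects, intercept_sd = intercept_sd,
         age_mean = age_mean, age_sd = age_sd, age_min = age_min,
         income_mean = income_mean, income_sd = income_sd,
         p_essential = p_essential, p_female = p_female,
         education_probs = education_probs,
         k_log10_mean = k_log10_mean, k_log10_sd = k_log10_sd,
         severity_shape1 = severity_shape1, severity_shape2 = severity_shape2,
         latent_cor = latent_cor, task = task),
    class = "cohort_spec"
  )
}

rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

#' Draw questionnaire item tables from latent severities
#'
#' Each participant has a latent severity in `[0, 1]`; every item rating is
#' drawn Binomial(max rating, severity), so severity 0 yields all-zero
#' responses and severity 1 yields the instrument maximum, with monotone
#' mean totals in between and totals correlated through the shared latent.
#'
#' @param severity Numeric vector in `[0, 1]`, one latent per participant.
#' @param instrument `"GAD7"`, `"PHQ9"`, or `"IUS12"`.
#' @return Integer matrix (participants x items) of ratings.
#' @export
distress_items <- function(severity, instrument = c("GAD7", "PHQ9", "IUS12")) {
  instrument <- match.arg(instrument)
  if (any(severity < 0 | severity > 1)) stop("`severity` must lie in [0, 1].")
  info <- instrument_info(instrument)
  n <- length(severity)
  matrix(stats::rbinom(n * info$n_items, info$max,
                       rep(severity, times = info$n_items)),
         nrow = n, ncol = info$n_items)
}

#' Generate a synthetic cohort through the full measurement pipeline
#'
#' Per participant: a country is drawn by weight (one Gaussian intercept per
#' country), covariates come from the spec's marginals, questionnaire items
#' are drawn from latent severities and scored with [score_instrument()] and
#' [distress_index()], and the AuC is measured by running a deterministic
#' hyperbolic agent (k from the spec's log-normal) through the titration
#' engine and [dd_auc_matrix()]. Age, relative income, distress and
#' intolerance of uncertainty are z-scored within the generated sample before
#' the linear predictor is formed; gender, education, essential-worker status
#' and AuC enter raw. The booster outcome is Bernoulli on the inverse-logit
#' of the linear predictor plus the country intercept.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; every draw in the generator flows from it.
#' @param keep_items Also return the raw GAD-7/PHQ-9/IUS-12 item matrices.
#' @param keep_trials Also return the per-trial titration logs (long format).
#' @return A list with `cohort` (one row per participant), `true_u` (country
#'   intercepts), and optionally `items` and `trial_log`.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L,
                            keep_items = FALSE, keep_trials = FALSE) {
  if (!inherits(spec, "cohort_spec")) stop("`spec` must be a cohort_spec.")
  set.seed(as.integer(seed))
  n <- spec$n
  country <- sample.int(spec$n_countries, n, replace = TRUE,
                        prob = spec$country_weights)
  u <- stats::rnorm(spec$n_countries, 0, spec$intercept_sd)

  age <- rtruncnorm(n, spec$age_mean, spec$age_sd, lower = spec$age_min)
  relative_income <- rtruncnorm(n, spec$income_mean, spec$income_sd, 0, 100)
  essential <- stats::rbinom(n, 1, spec$p_essential)
  gender <- stats::rbinom(n, 1, spec$p_female)  # female = 1
  education <- sample(0:2, n, replace = TRUE, prob = spec$education_probs)

  # correlated latent severities on the Gaussian copula scale
  z1 <- stats::rnorm(n)
  z2 <- spec$latent_cor * z1 + sqrt(1 - spec$latent_cor^2) * stats::rnorm(n)
  sev_distress <- stats::qbeta(stats::pnorm(z1),
                               spec$severity_shape1, spec$severity_shape2)
  sev_ius <- stats::qbeta(stats::pnorm(z2),
                          spec$severity_shape1, spec$severity_shape2)
  gad7_items <- distress_items(sev_distress, "GAD7")
  phq9_items <- distress_items(sev_distress, "PHQ9")
  ius12_items <- distress_items(sev_ius, "IUS12")
  gad7_total <- score_instrument(gad7_items, "GAD7")
  phq9_total <- score_instrument(phq9_items, "PHQ9")
  ius12_total <- score_instrument(ius12_items, "IUS12")
  distress <- distress_index(gad7_total, phq9_total)

  # discounting: deterministic hyperbolic agents through the titration engine
  k <- 10^stats::rnorm(n, spec$k_log10_mean, spec$k_log10_sd)
  days <- spec$task$delays$days
  sv <- spec$task$delayed_amount / (1 + outer(k, days))
  iv <- matrix(NA_real_, n, length(days))
  trial_rows <- if (keep_trials) vector("list", length(days)) else NULL
  for (j in seq_along(days)) {
    res <- titrate_threshold(sv[, j], spec$task, keep_trials = keep_trials)
    if (keep_trials) {
      iv[, j] <- res$indifference
      trial_rows[[j]] <- data.frame(
        participant_id = rep(seq_len(n), times = spec$task$n_trials),
        delay_label = spec$task$delays$label[j],
        delay_days = days[j],
        trial_index = rep(seq_len(spec$task$n_trials), each = n),
        immediate_offer = as.vector(res$offers),
        choice = as.vector(res$choices),
        stringsAsFactors = FALSE
      )
    } else {
      iv[, j] <- res
    }
  }
  auc <- dd_auc_matrix(iv, days, spec$task$delayed_amount)

  b <- spec$fixed_effects
  eta <- b[["intercept"]] +
    b[["age"]] * as.numeric(scale(age)) +
    b[["gender"]] * gender +
    b[["education"]] * education +
    b[["relative_income"]] * as.numeric(scale(relative_income)) +
    b[["essential"]] * essential +
    b[["distress"]] * as.numeric(scale(distress)) +
    b[["ius"]] * as.numeric(scale(ius12_total)) +
    b[["auc"]] * auc +
    u[country]
  booster <- stats::rbinom(n, 1, stats::plogis(eta))

  cohort <- data.frame(
    participant_id = seq_len(n),
    country = factor(paste0("C", sprintf("%02d", country))),
    age = age, gender = gender, education = education,
    relative_income = relative_income, essential = essential,
    gad7_total = gad7_total, phq9_total = phq9_total,
    ius12_total = ius12_total, distress = distress,
    k = k, auc = auc,
    vaccination_status = 1L,          # the modelled sample is vaccinated
    booster_raw = booster,
    attention_pass = TRUE,
    stringsAsFactors = FALSE
  )
  cohort <- code_outcomes(cohort)
  iv_df <- data.frame(
    participant_id = rep(seq_len(n), times = length(days)),
    delay_days = rep(days, each = n),
    subjective_value = as.vector(iv)
  )
  out <- list(cohort = cohort, indifference = iv_df, true_u = u, spec = spec)
  if (keep_items) {
    out$items <- list(gad7 = gad7_items, phq9 = phq9_items, ius12 = ius12_items)
  }
  if (keep_trials) out$trial_log <- do.call(rbind, trial_rows)
  out
}
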