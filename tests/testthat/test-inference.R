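test_that("scale_predictors z-scores the named columns and records constants", {
  d <- data.frame(a = c(1, 2, 6), b = c(10, 10, 10), c = letters[1:3])
  out <- scale_predictors(d, "a")
  expect_equal(out$a, (c(1, 2, 6) - 3) / 2.6457513110645907)
  expect_equal(attr(out, "scaling")$center, 3)
  expect_equal(attr(out, "scaling")$sd, sd(c(1, 2, 6)))
  already <- data.frame(a = as.numeric(scale(rnorm(20))))
  expect_equal(scale_predictors(already, "a")$a, already$a, tolerance = 1e-12)
  expect_error(scale_predictors(d, "b"), "zero variance")
  expect_error(scale_predictors(d, "c"), "not numeric")
})

test_that("OR and CI columns are exact transforms of b and SE", {
  g <- generate_cohort(cohort_spec(n = 800), seed = 101)
  f <- fit_booster_glmm(g$cohort)
  expect_equal(f$coefficients$or, exp(f$coefficients$b))
  expect_equal(f$coefficients$ci_low, exp(f$coefficients$b - 1.96 * f$coefficients$se))
  expect_equal(f$coefficients$ci_high, exp(f$coefficients$b + 1.96 * f$coefficients$se))
  expect_true(all(f$coefficients$ci_low <= f$coefficients$or &
                    f$coefficients$or <= f$coefficients$ci_high))
  expect_identical(f$n_obs, 800L)
  expect_identical(f$n_groups, 13L)
})

test_that("zero group variance collapses to ordinary logistic regression", {
  g <- generate_cohort(cohort_spec(n = 2000, intercept_sd = 0), seed = 103)
  f <- suppressMessages(fit_booster_glmm(g$cohort))
  expect_lt(f$intercept_sd, 0.02)
  sc <- scale_predictors(g$cohort, default_scaled())
  oracle <- stats::glm(
    booster_willing ~ age + gender + education + relative_income + essential +
      distress + ius12_total + auc,
    data = sc, family = binomial())
  expect_equal(f$coefficients$b, unname(coef(oracle)), tolerance = 1e-4)
})

test_that("marginal likelihood matches dense integration on a small dataset", {
  d <- data.frame(y = c(1, 1, 1, 0, 1, 1, 0, 0, 1, 0, 0, 0),
                  x = c(0.2, -1, 0.5, 1.2, -0.3, 0.8,
                        -0.7, 0.3, 1.5, -1.2, 0.4, 0.9),
                  g = rep(c("a", "b"), each = 6))
  loglik_oracle <- function(fit) {
    b <- lme4::fixef(fit)
    s <- sqrt(as.data.frame(lme4::VarCorr(fit))$vcov[1])
    sum(vapply(split(d, d$g), function(dd) {
      f1 <- function(u) vapply(u, function(ui) {
        p <- plogis(b[1] + b[2] * dd$x + ui)
        prod(p^dd$y * (1 - p)^(1 - dd$y)) * dnorm(ui, 0, s)
      }, numeric(1))
      log(stats::integrate(f1, -Inf, Inf, rel.tol = 1e-13)$value)
    }, numeric(1)))
  }
  fits <- lapply(c(1, 5, 25), function(q) {
    lme4::glmer(y ~ x + (1 | g), data = d, family = binomial(), nAGQ = q)
  })
  errs <- vapply(fits, function(f) {
    abs(as.numeric(logLik(f)) - loglik_oracle(f))
  }, numeric(1))
  # refinement moves the approximate likelihood monotonically to the oracle
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-6)
})

test_that("the likelihood-ratio test follows the chi-square arithmetic", {
  g <- generate_cohort(cohort_spec(n = 1200), seed = 107)
  res <- pipeline_fit(g$cohort)
  expect_identical(res$lrt$df, 8L)
  expect_equal(res$lrt$statistic,
               2 * (res$fit$log_likelihood - res$null$log_likelihood))
  expect_equal(res$lrt$p,
               pchisq(res$lrt$statistic, 8, lower.tail = FALSE))
  # identical models -> statistic 0, p 1
  same <- lrt(res$fit, res$fit)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # row-mismatched models are refused
  g2 <- generate_cohort(cohort_spec(n = 600), seed = 109)
  other <- fit_booster_glmm(g2$cohort, predictors = NULL, scale_vars = character())
  expect_error(lrt(res$fit, other), "different numbers of rows")
})

test_that("fit validation: binary outcome, >= 2 groups, listwise deletion", {
  g <- generate_cohort(cohort_spec(n = 300), seed = 113)
  co <- g$cohort
  co$booster_willing[1:10] <- NA
  f <- fit_booster_glmm(co)
  expect_identical(f$n_obs, 290L)
  bad <- co; bad$booster_willing <- bad$booster_willing + 1
  expect_error(fit_booster_glmm(bad), "binary")
  one <- co; one$country <- factor("C01")
  expect_error(fit_booster_glmm(one), "2 groups")
  const <- co; const$auc <- 0.5
  expect_error(fit_booster_glmm(const, scale_vars = c("auc")), "zero variance")
})

test_that("group discounting curves summarize means and SEs per delay", {
  sim <- pipeline_simulate_task(60, seed = 115)
  outcomes <- data.frame(participant_id = 1:60,
                         booster_willing = rep(c(0, 1), each = 30))
  gc <- group_curves(sim$indifference, outcomes)
  expect_identical(nrow(gc), 14L)
  expect_true(all(gc$n == 30))
  # identical groups -> identical curves
  outcomes2 <- data.frame(participant_id = 1:60,
                          booster_willing = rep(c(0, 1), 30))
  iv_dup <- sim$indifference
  iv_dup$subjective_value <- rep(iv_dup$subjective_value[iv_dup$participant_id <= 2][1],
                                 nrow(iv_dup))
  gc2 <- group_curves(iv_dup, outcomes2)
  expect_equal(gc2$mean_sv[gc2$group == 0], gc2$mean_sv[gc2$group == 1])
  # SE matches the textbook formula on one cell
  cell <- sim$indifference[sim$indifference$delay_days == 365 &
                             sim$indifference$participant_id <= 30, ]
  expect_equal(gc$se_sv[gc$group == 0 & gc$delay_days == 365],
               sd(cell$subjective_value) / sqrt(30))
  expect_error(group_curves(sim$indifference,
                            data.frame(participant_id = 1:60,
                                       booster_willing = NA)),
               "non-missing")
})

test_that("low-k and high-k groups give ordered curves at every delay", {
  cfg <- task_config()
  sim_group <- function(k, ids) {
    days <- cfg$delays$days
    iv <- vapply(days, function(D) {
      titrate_threshold(rep(2000 / (1 + k * D), length(ids)), cfg)
    }, numeric(length(ids)))
    data.frame(participant_id = rep(ids, times = length(days)),
               delay_days = rep(days, each = length(ids)),
               subjective_value = as.vector(iv))
  }
  iv <- rbind(sim_group(0.002, 1:20), sim_group(0.05, 21:40))
  outcomes <- data.frame(participant_id = 1:40,
                         booster_willing = rep(c(1, 0), each = 20))
  gc <- group_curves(iv, outcomes)
  willing <- gc[gc$group == 1, ]
  unwilling <- gc[gc$group == 0, ]
  expect_true(all(willing$mean_sv > unwilling$mean_sv))
})
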