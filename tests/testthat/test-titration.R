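test_that("initial state presents half the amount with a half-difference step", {
  cfg <- task_config()
  s <- titration_start(cfg, "3 years")
  expect_equal(s$offer, 1000)
  expect_equal(s$step, 500)
  expect_identical(s$trials_done, 0L)
  expect_identical(nrow(s$history), 0L)

  s2 <- titration_start(task_config(delayed_amount = 100, initial_immediate = 50),
                        list(label = "1 day", days = 1))
  expect_equal(s2$offer, 50)
  expect_equal(s2$step, 25)
  s3 <- titration_start(task_config(delayed_amount = 2000, initial_immediate = 1500),
                        list(label = "1 day", days = 1))
  expect_equal(s3$offer, 1500)
  expect_equal(s3$step, 250)
})

test_that("config invariants are enforced", {
  expect_error(task_config(initial_immediate = 2000), "strictly between")
  expect_error(task_config(initial_immediate = 0), "strictly between")
  expect_error(task_config(n_trials = 0), ">= 1")
  d <- delay_conditions()
  d$days[2] <- 5  # not increasing
  expect_error(task_config(delays = d), "strictly increasing")
})

test_that("choices move the offer by the current step and halve it", {
  s <- titration_start(task_config(), "3 years")
  s <- titration_choose(s, "delayed")
  expect_equal(s$offer, 1500)
  expect_equal(s$step, 250)
  s <- titration_choose(s, "immediate")
  expect_equal(s$offer, 1250)
  expect_equal(s$step, 125)
  s0 <- titration_start(task_config(), "1 week")
  s0 <- titration_choose(s0, "immediate")
  expect_equal(s0$offer, 500)
  # one-letter log codes accepted
  s1 <- titration_choose(titration_start(task_config(), "1 week"), "D")
  expect_equal(s1$offer, 1500)
})

test_that("extra choices after the final trial are rejected", {
  s <- titration_start(task_config(), "1 week")
  for (i in 1:6) s <- titration_choose(s, "delayed")
  expect_error(titration_choose(s, "delayed"), "already completed")
})

test_that("indifference point equals the hypothetical next offer", {
  run <- function(choices) {
    s <- titration_start(task_config(), "1 month")
    for (ch in choices) s <- titration_choose(s, ch)
    indifference_point(s)$subjective_value
  }
  expect_equal(run(rep("delayed", 6)), 1984.375)
  expect_equal(run(rep("immediate", 6)), 15.625)
  expect_equal(run(c("D", "I", "I", "D", "D", "D")), 1234.375)
  # incomplete condition
  s <- titration_choose(titration_start(task_config(), "1 month"), "D")
  expect_error(indifference_point(s), "incomplete")
})

test_that("indifference point is a pure function of the choice sequence", {
  set.seed(11)
  for (r in 1:25) {
    choices <- sample(c("D", "I"), 6, replace = TRUE)
    s <- titration_start(task_config(), "1 year")
    for (ch in choices) s <- titration_choose(s, ch)
    expect_equal(indifference_point(s)$subjective_value, oracle_replay(choices))
  }
})

test_that("applied step on trial t is (A - I0)/2^t and offers stay in bounds", {
  set.seed(21)
  for (r in 1:20) {
    choices <- sample(c("D", "I"), 6, replace = TRUE)
    s <- titration_start(task_config(), "6 months")
    prev_offer <- s$offer
    for (t in seq_along(choices)) {
      s <- titration_choose(s, choices[t])
      expect_equal(abs(s$offer - prev_offer), 1000 / 2^t)
      prev_offer <- s$offer
    }
    expect_true(all(s$history$immediate_offer >= 31.25),
                info = paste(choices, collapse = ""))
    expect_true(all(s$history$immediate_offer <= 1968.75))
    sv <- indifference_point(s)$subjective_value
    expect_gte(sv, 15.625)
    expect_lte(sv, 1984.375)
  }
})

test_that("run_condition converges for threshold responders and logs all trials", {
  cfg <- task_config()
  r <- responder("fixed_threshold", threshold = 1250)
  res <- run_condition(r, cfg, "3 years")
  expect_identical(nrow(res$trials), 6L)
  expect_lte(abs(res$point$subjective_value - 1250), 15.625)
  expect_equal(run_condition(responder("always_delayed"), cfg,
                             "1 week")$point$subjective_value, 1984.375)
  expect_equal(run_condition(responder("always_immediate"), cfg,
                             "1 week")$point$subjective_value, 15.625)
})

test_that("run_task yields one point per delay and a full log", {
  p <- run_task(responder("hyperbolic", k = 0.005), task_config())
  expect_identical(nrow(p$points), 7L)
  expect_identical(nrow(p$trials), 42L)
  expect_true(!is.unsorted(p$points$days, strictly = TRUE))
  single <- task_config(delays = data.frame(label = "1 year", days = 365))
  p1 <- run_task(responder("hyperbolic", k = 0.005), single)
  expect_identical(nrow(p1$points), 1L)
  expect_identical(nrow(p1$trials), 6L)
  pd <- run_task(responder("always_delayed"), task_config())
  expect_true(all(pd$points$subjective_value == 1984.375))
})

test_that("shuffled administration order leaves the profile unchanged", {
  r <- responder("hyperbolic", k = 0.02)
  p1 <- run_task(r, task_config())
  set.seed(4)
  p2 <- run_task(r, task_config(), shuffle_delays = TRUE)
  expect_equal(p2$points, p1$points)
  expect_equal(p2$auc, p1$auc)
})

test_that("vectorized threshold titration matches the scalar state machine", {
  cfg <- task_config()
  set.seed(31)
  v <- runif(40, 0, 2000)
  batch <- titrate_threshold(v, cfg)
  scalar <- vapply(v, function(vi) {
    run_condition(responder("fixed_threshold", threshold = vi), cfg,
                  "1 year")$point$subjective_value
  }, numeric(1))
  expect_equal(batch, scalar)
  # trial detail agrees with replay
  det <- titrate_threshold(v[1:5], cfg, keep_trials = TRUE)
  for (i in 1:5) {
    expect_equal(oracle_replay(det$choices[i, ]), det$indifference[i])
  }
})

test_that("offers can be rounded to a configured currency precision", {
  cfg <- task_config(currency_precision = 0)
  s <- titration_start(cfg, "1 week")
  for (ch in c("D", "D", "D")) s <- titration_choose(s, ch)
  expect_true(all(s$history$immediate_offer == round(s$history$immediate_offer)))
})
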